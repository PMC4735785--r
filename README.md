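# svfusion

Patient-specific genomic breakpoint detection for the ETV6-RUNX1
fusion — the t(12;21)(p13;q22) translocation of childhood B-lineage
acute lymphoblastic leukemia — from targeted-capture paired-end
sequencing, with the genetic interpretation and cohort statistics that
go with it.

The fusion transcript is the same in every patient, but the *genomic*
breakpoint is scattered over tens of kilobases of ETV6 intron 5 and
RUNX1 introns 1–3, making the fused DNA sequence a patient-specific,
clonally stable marker for minimal residual disease (MRD). `svfusion`
finds that sequence: read pairs are classified against a robust
insert-size model (median / 1.4826·MAD of concordant FR separations);
pairs with both mapping qualities above 30 that are inter-chromosomal,
wrongly oriented, or separated by more than 4 standard deviations are
clustered into candidate breakpoints; reads within 500–1000 bp of each
prediction are assembled into a junction contig by greedy overlap
consensus; and the contig is resolved to base-pair precision — maximal
exact prefix and suffix matches to the reference, their overlap the
microhomology, any gap the untemplated insertion. A read supports a
junction only if it crosses the joint by at least 2 bases on both
sides, has fewer than 5 unaligned bases at either end, and is not
fully explained by one reference locus.

On top of the caller:

* **Orientation typing** — a chr12-donor/chr21-acceptor junction is
  typed by its strand pair: FF → a, RR → b, FR → c (the classic
  fusion), RF → d (the reciprocal product).
* **Derivative chromosomes** — segment reconstruction with centromere
  counting: type a products are acentric (hence never observed), type
  b dicentric, c/d monocentric.
* **Event interpretation** — reciprocal two-way, three-way (a third
  chromosome captures the displaced ETV6/RUNX1 remainders), and joint
  homologous-chromosome breaks.
* **FISH prediction** — expected extra-signal dual-colour patterns per
  karyotype under a probe-interval model.
* **Clone comparison** — diagnosis vs relapse callsets compared by
  canonical breakends plus fused flanking sequence.
* **Cohort statistics** — orientation census, three-way detection,
  capture-region arithmetic, Kaplan–Meier curves with a
  first-principles two-group log-rank test, and an exact
  hypergeometric association test.
* **MRD export** — fused breakpoint ± flank FASTA records ready for
  qPCR assay design.
* **Simulator** — deterministic toy genomes, derivative chromosomes
  with engineered microhomology/insertions, and capture-enriched
  paired reads (truncated-normal inserts, pair-level capture
  emulation) with machine-readable truth.

## Worked example

Simulate a reciprocal t(12;21)-like event on a toy genome (4 bp of
engineered microhomology on the first junction), map the reads with
the built-in k-mer mapper, and call:

```r
library(svfusion)

gm <- makeToyGenome(c(chr12toy = 50000, chr21toy = 60000),
    centromeres = list(chr12toy = c(40000, 41000),
                       chr21toy = c(5000, 6000)),
    targetRegions = data.frame(chrom = c("chr12toy", "chr21toy"),
                               start = c(18500, 30500),
                               end = c(21500, 33500)),
    seed = 101)
truth <- applyJunctions(gm,
    list(Junction(Breakend("chr12toy", 20000, "F"),
                  Breakend("chr21toy", 32000, "R")),
         Junction(Breakend("chr12toy", 20001, "R"),
                  Breakend("chr21toy", 32001, "F"))),
    homologyLen = c(4, 0))
reads <- simulateReads(truth, SimulationConfig(seed = 101))
aln   <- builtinMap(reads, truth@genome)
calls <- callSample(aln, truth@genome, sample = "patient01")
calls
#> SampleCallset 'patient01' with 2 junction(s)
#> Junction chr12toy:20,000(F) -> chr21toy:32,000(R)  hom=4 ins=0bp  pairs=24 split=21
#> Junction chr12toy:20,001(R) -> chr21toy:32,001(F)  hom=4 ins=0bp  pairs=25 split=24
```

Both truth junctions come back at their exact coordinates, the first
with its 4 bp microhomology, each backed by ~25 discordant pairs and
~20 split reads. Interpretation recognizes the balanced event and
reconstructs its derivatives:

```r
ev <- interpretEvents(junctions(calls),
                      primaryPair = c("chr12toy", "chr21toy"),
                      genome = truth@genome)
ev[[1]]
#> RearrangementEvent <two_way_reciprocal> with 2 junction(s)
derivatives(ev[[1]])[[1]]
#> DerivativeChromosome chr12toy:1-20000(fwd) + chr21toy:1-32000(revcomp)  [monocentric]
```

The packaged clinical fixtures reproduce the cohort-level picture —
26 patients (20 boys, mean age 5.1 y); type census a:0, b:1, c:23,
d:16 with both c and d in 13 patients; five three-way patients
(partners chr5, chr5, chr6, chr8, chr15); and a log-rank p of
3.1×10⁻⁵ for relapse-free survival by three-way status, with the
companion exact tail probability 5/14,950:

```r
tbl <- readJunctionTable(system.file("extdata", "table2_junctions.tsv",
                                     package = "svfusion"))
countTypes(tbl)$counts
#>  a  b  c  d
#>  0  1 23 16
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/svfusion` (subcommands `simulate`, `call`, `interpret`,
`cohort`, `compare`, `export-mrd`).

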