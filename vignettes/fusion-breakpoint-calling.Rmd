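---
title: "Calling patient-specific ETV6-RUNX1 genomic breakpoints from targeted capture sequencing"
author: "svfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling patient-specific ETV6-RUNX1 genomic breakpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svfusion)
```

# The problem

The t(12;21)(p13;q22) translocation fuses the 5′ portion of *ETV6*
(chromosome 12, intron 5) to nearly the whole *RUNX1* locus (chromosome
21, introns 1–3) and is the most common gene fusion in childhood
B-lineage acute lymphoblastic leukemia. The fusion *transcript* is well
characterized, but the *genomic* breakpoint is scattered across tens of
kilobases of intron and is therefore different in every patient. That
patient-specific fused DNA sequence is an ideal marker for minimal
residual disease (MRD): it is stable across the disease course,
amplifiable by qPCR, and unique to the leukemic clone.

`svfusion` implements a desk-scale version of the laboratory's
informatic pipeline around that idea: capture-enriched paired-end reads
over the *ETV6*/*RUNX1* breakpoint regions are screened for
inter-chromosomal and discordant read pairs, candidate breakpoints are
assembled from junction-spanning reads, and each junction is resolved
to base-pair precision with its microhomology and untemplated inserted
bases. Downstream, junctions are interpreted genetically (orientation
types, derivative chromosomes, two-way/three-way events, FISH signal
predictions, diagnosis/relapse clone comparisons) and summarized at
cohort level (orientation census, Kaplan–Meier/log-rank survival by
three-way status, exact hypergeometric association).

# Junction model and strand semantics

A **breakend** is a chromosome, a 1-based position and a strand flag
`F`/`R`; a **junction** joins a *donor* breakend (sequence flowing into
the joint) to an *acceptor* breakend (flowing out). The fused molecule
is

> donor segment + untemplated insertion + acceptor segment,

with segments defined as: donor `F` → forward prefix `[1..pos]`; donor
`R` → reverse complement of the suffix `[pos..len]`; acceptor `F` →
forward suffix `[pos..len]`; acceptor `R` → reverse complement of the
prefix `[1..pos]`. A junction equals its mirror
`((c1,p1,s1),(c2,p2,s2)) → ((c2,p2,s̄2),(c1,p1,s̄1))`; the canonical
form puts the donor on the earlier chromosome in natural order, so
junction identity is well defined.

For a chr12-donor/chr21-acceptor junction the strand pair defines the
four orientation **types**: `FF → a`, `RR → b`, `FR → c` (the classic
ETV6-RUNX1 fusion), `RF → d` (its reciprocal product). Types are not
merely labels: reconstructing the derivative chromosome and counting
the centromeres its segments overlap shows type a derivatives are
acentric (mitotically nonviable — the model's explanation for why no
type a is ever observed), type b derivatives are dicentric, and types
c/d are monocentric. Any ≥1 bp overlap with an annotated centromere
interval counts, since the argument is qualitative presence/absence.

Type counting for cohort statistics includes every chr12–chr21
junction, whether or not both breakends fall inside the capture
intervals; two patients in the packaged tables carry a chr12/chr21
breakend well outside the capture regions that is still part of the
reciprocal product.

# The calling procedure

1. **Insert-size model.** Separations (outer span, rightmost aligned
   base − leftmost + 1) of co-chromosomal inward-facing FR pairs give
   the model: center = median, spread = 1.4826·MAD. The median/MAD pair
   is robust to the contamination the discordant pairs themselves
   introduce. A coarse-histogram mode count (3-bin moving average; two
   maxima are distinct modes only when the valley between them drops
   below half the lower peak) flags non-unimodal libraries.
2. **Pair classes.** A pair is `low_quality` unless both mates map with
   quality strictly above 30; `interchromosomal` when the mates map to
   different chromosomes; `discordant_orientation` when not
   inward-facing FR; `discordant_distance` when its separation deviates
   from the center by more than 4 spreads. Deviation is two-sided —
   the procedure's wording covers only excess separation, but the
   two-sided form also catches deletion-like artifacts and costs
   nothing in specificity at 4 SD.
3. **Clustering.** SV-evidence pairs are grouped by (ordered chromosome
   pair, orientation class) and single-linkage chained with positional
   gap ≤ center + 3·spread on both footprints. Clusters need
   ≥ `minClusterPairs` (default 3) members. Predicted breakends are the
   innermost mate-end coordinates: the junction lies right of a `+`
   footprint and left of a `-` footprint, which also fixes the breakend
   strand flags.
4. **Window extraction.** All mapped reads within `windowBp`
   (500–1000, default 750) of each predicted breakend are pulled,
   plus unmapped reads whose mates map inside a window.
5. **Assembly.** Junction contigs are built by greedy overlap
   consensus: the longest read (ties broken lexicographically) seeds a
   contig; each round merges the read with the highest-scoring overlap
   (≥30 bp at ≥0.95 identity, both orientations considered, candidates
   via shared 21-mers); per-column base counts give a majority
   consensus, which corrects scattered sequencing errors. Only clipped
   reads consistent with the cluster's orientation class (the clip must
   face the predicted junction) and unmapped mates enter assembly —
   otherwise reads from a reciprocal junction a few bases away would
   contaminate the pool. Disjoint read groups are assembled separately
   and the group with the most reads wins (a handful of
   coincidentally-clipped reference reads can otherwise out-lengthen
   the true junction contig).
6. **Resolution.** The maximal exact match of the contig's prefix to
   one reference locus (either strand) and of its suffix to another
   are found by exact 25-mer anchoring plus bidirectional extension;
   collinear follow-up matches (same chromosome, strand and diagonal)
   are merged across isolated consensus errors. Overlap of the two
   matches is the microhomology; a gap is the untemplated insertion. A
   contig whose two matches share one diagonal is the reference allele.
7. **Support counting.** A read supports the junction iff it aligns to
   the contig across the junction zone with at least `minCrossBases`
   (default 2) bases beyond the joint on both sides, leaves fewer than
   5 unaligned bases at each read end, and is not fully explained by a
   single reference locus. "Not explained by the reference" is
   operationalized as *its best single-locus alignment leaves clipped
   bases* — the literal reading (no reference alignment at all) would
   reject every junction-spanning read with one long mapped side.
   Junctions with ≥ `minSupportReads` (default 2) split reads are
   emitted, with the discordant cluster size as pair-level support.

## Breakpoint convention under microhomology

When `h` bases at the joint are shared by both sides, the breakpoint is
ambiguous over `h + 1` placements. Calls are reported at the placement
with the smallest donor coordinate (leftmost-donor convention), and the
homology length is recorded so equivalent placements can be
reconstructed. The published coordinate table does not state its own
convention, so its coordinates are treated as data (fixtures), not
re-derived. Internally, resolution yields the donor-minimal placement
in the contig's own orientation; mirroring into canonical form lands on
the donor-maximal end exactly when the two strand flags differ, and the
placement is slid back in that case.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `mqMin` | 30 | Phred | strict mapping-quality floor for SV evidence |
| `kSd` | 4 | spreads | separation deviation bound |
| `windowBp` | 750 | bp | read-extraction half window (500–1000 allowed) |
| `maxUnalignedEndBp` | 5 | bp | exclusive bound on unaligned read-end bases |
| `minCrossBases` | 2 | bp | bases required beyond the junction per side |
| `minClusterPairs` | 3 | pairs | discordant-cluster floor |
| `minSupportReads` | 2 | reads | split-read support floor |
| `asmMinOverlap` / `asmMinIdentity` | 30 / 0.95 | bp / fraction | assembly merge thresholds |
| `flankBp` | 300 | bp | flank attached to calls and MRD exports |

The quality, window, end-base and crossing thresholds are the
procedure's stated values and behave literally at their boundaries (MQ
30 excluded / 31 included, 4·SD concordant / >4·SD discordant, 1
crossing base rejected / 2 accepted, 4 end bases accepted / 5
rejected). The cluster and support floors are this package's
specificity choices — the original write-up states no minima — and are
exposed as parameters everywhere (API and command line).

# The read simulator

The generator emulates the assay the caller targets: a 350–400 bp
size-selected library sequenced as 100 bp paired reads over
hybridization-capture targets. Its defaults are therefore insert mean
375 bp, insert SD 35 bp, read length 100 bp, 30× target coverage.
Fragment lengths are truncated-normal (floored at 2·readLen) — a
lognormal would also be defensible, but the unimodal symmetric model
keeps the 4·SD rule well defined. Capture is emulated at the pair
level: the on-target pair count is `depth · targetBp / (2 · readLen)`,
fragment placements are drawn uniformly from the positions overlapping
a target (lifted into derivative coordinates) ± `captureMargin`
(500 bp), and `offTargetRate` (5%) of pairs are drawn genome-wide.
Errors are uniform substitutions at a flat Phred quality; no PCR
duplicates, adapters, indel errors or quality profiles are modeled.
Every function takes a mandatory seed; the same seed reproduces output
byte for byte.

Requested microhomology is made *real*: the `h` acceptor-side bases
that follow the joint are copied onto the donor's reference
continuation, so the junction is genuinely ambiguous over `h + 1`
placements in the edited genome (which the truth set carries).
Requesting microhomology together with an untemplated insertion is
rejected as contradictory.

What passing simulation tests do **not** show: performance on real
capture data with indel sequencing errors, PCR chimeras, repetitive
intronic sequence (toy genomes are i.i.d. random, so 21-mer anchors are
effectively unique), tumor purity below ~50%, or breakpoints inside
low-complexity tracts. The built-in k-mer mapper is a test convenience
for ≤1 Mbp references; externally aligned SAM/BAM is the first-class
input for real data.

# Cohort statistics

The packaged tables (26 patients; 50 junction rows; relapse
comparisons for the four relapsed patients) are transcribed verbatim
from the published clinical and breakpoint tables, including their
typographic quirks: thousands separators are tolerated (and sometimes
misplaced) on read and never written, and the one chr21 coordinate
printed outside the capture region (38,264,151, almost certainly a
typo for 36,264,151) is stored as printed with the corrected value in
a separate column; computations use the printed value, which does not
affect any census (type counting uses the strand columns only).

Survival uses the remission-time column as time-to-event for relapsed
patients and as censoring time for patients in remission — the only
reading consistent with the four relapse days matching the narrative.
The published analysis names Kaplan–Meier and a p-value bound; the
two-group log-rank test is the standard companion and is implemented
from first principles (per-event-time hypergeometric expectation and
variance, chi-square with 1 df), with `survival::survdiff` as an
independent cross-check in the tests only. The companion exact
association test enumerates the hypergeometric tail with binomial
coefficients and is tested against brute-force subset enumeration.
Mean age is rounded half-up to one decimal.

# FISH pattern prediction

The extra-signal dual-colour probe pair (green over 5′ *ETV6*, red over
*RUNX1*) is modeled as intervals with a minimum detectable fragment
size. Under diploidy, each event consumes one homologue of every
chromosome its breakends touch; every remaining native homologue and
every derivative is scanned for probe content, fragments under the
detection floor are invisible, and a chromosome carrying detectable
fragments of both colours yields a single colocalized (yellow) signal.
This reproduces the negative pattern (2 green, 2 red) and the classic
fusion pattern (1 green, 2 red — one large, one small — 1 yellow). Two
published patterns are deliberately not asserted: the homozygous "two
red, two yellow" pattern of the patient with joint homologous breaks
(not derivable from the b+d junction set without the homozygosity
assumption, which the model records but cannot infer), and the
three-red three-way pattern (not fully derivable from the stated probe
model).

# Numerical and engineering choices

* Alignment scoring is ungapped +1/−2 along seeded diagonals with the
  best local segment found by prefix-sum minimization; soft clips are
  the bases outside that segment. Mapping quality is 60 (unique best),
  3 (tied best — a stand-in policy; the original analysis predates any
  statement on multi-mapper handling), 0 (unmapped).
* All k-mers are 2-bit packed into doubles (k = 21 ≪ the 26-base limit
  of exact double arithmetic); reference lookups go through one sorted
  vector with batched binary searches.
* Assembly consensus ties break towards the alphabetically first base;
  merge ties towards the lexicographically smaller read; both keep the
  assembler deterministic.
* Coordinates are 1-based inclusive everywhere in the API and file
  formats except BED (0-based half-open, converted at the boundary).
  VCF breakend ALT strings follow the bracket notation with the mate
  record given by the mirror transform.
* Degenerate inputs: empty callsets compare as `identical`; a contig
  explainable by one locus is a reference allele, not a junction; a
  degenerate FISH panel yields all-zero counts; insert-model
  estimation refuses fewer than 100 usable pairs.

# Problem sizes

The simulation test battery uses three-chromosome toy genomes of
150 kbp with two 3 kbp capture targets, 30× target coverage, 100 bp
reads, inserts N(375, 35) and 0.5% base error — 20 seeded replicates
for each of six rearrangement scenarios (lone type c, reciprocal c+d,
homologous b+d, three-way, microhomology 0–8 bp, insertion 0–10 bp)
plus 20 SV-free controls, chosen so the whole battery runs in a few
minutes while every component still sees realistic evidence densities
(~25–35 discordant pairs and ~20–30 junction-crossing reads per
junction).

# Known limitations

* No intra-chromosomal deletion/inversion/insertion calling, no
  genotyping, no copy-number analysis.
* The caller requires split-read support with cluster corroboration;
  whether the original analysis accepted pair-only evidence is
  unstated, so both floors are parameters.
* Cytogenetic names like t(12;15;21)(p13;q25;q22) are echoed from
  input metadata, never computed from band coordinates.
* The FISH predictor is interval arithmetic, not hybridization
  physics; probe gaps and cross-hybridization are out of scope.
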