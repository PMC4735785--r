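# Shared fixtures: toy genomes, pipeline drivers and placement helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

# three-chromosome toy genome with centromeres and two capture targets
toyGenome <- function(seed = 11, targetHalf = 1500) {
    makeToyGenome(
        c(chrA = 50000, chrB = 60000, chrC = 40000),
        centromeres = list(chrA = c(40000, 41000), chrB = c(5000, 6000),
                           chrC = c(2000, 3000)),
        targetRegions = data.frame(
            chrom = c("chrA", "chrB"),
            start = c(20000 - targetHalf, 32000 - targetHalf),
            end = c(20000 + targetHalf, 32000 + targetHalf)),
        seed = seed)
}

# tiny two-chromosome genome used for derivative/FISH unit tests
miniGenome <- function() {
    GenomeModel(
        c(chrX = 1000, chrY = 1000),
        centromeres = GenomicRanges::GRanges(
            c("chrX", "chrY"),
            IRanges::IRanges(c(600, 100), c(650, 150))))
}

# run the full simulate -> map -> call pipeline on one truth set
runPipeline <- function(genome, junctions, seed, homologyLen = 0,
                        insertionSeq = "", errorRate = 0.005,
                        params = SvCallingParams()) {
    ts <- applyJunctions(genome, junctions, homologyLen = homologyLen,
                         insertionSeq = insertionSeq)
    reads <- simulateReads(ts, SimulationConfig(
        seed = seed, baseErrorRate = errorRate))
    aln <- builtinMap(reads, ts@genome)
    list(truth = ts,
         callset = callSample(aln, ts@genome, params = params,
                              sample = sprintf("sim%d", seed)))
}

# Does a called junction describe the same fused molecule as the truth
# junction? Two descriptions are equivalent iff the fused sequence the
# called junction implies (donor flank + insertion + acceptor flank,
# reconstructed from the genome) is a substring of the true derivative
# sequence around the truth junction. This accepts any placement
# within the real homology interval (including coincidental homology)
# and insertion-vs-shift ambiguities, and nothing else.
matchesTruth <- function(called, truth, genome) {
    ext <- tryCatch(junctionSequence(truth, genome, flankBp = 80)$seq,
                    error = function(e) return(NULL))
    win <- tryCatch(junctionSequence(called, genome, flankBp = 50)$seq,
                    error = function(e) return(NULL))
    if (is.null(ext) || is.null(win)) return(FALSE)
    grepl(win, ext, fixed = TRUE) ||
        grepl(svfusion:::revcomp(win), ext, fixed = TRUE)
}

expectRecovered <- function(callset, truthset, genome) {
    for (truth in junctions(truthset)) {
        hit <- any(vapply(junctions(callset), matchesTruth, logical(1),
                          truth = truth, genome = genome))
        expect_true(hit, label = sprintf(
            "truth junction %s recovered", svfusion:::junctionKey(truth)))
    }
    expect_length(junctions(callset), length(junctions(truthset)))
}
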