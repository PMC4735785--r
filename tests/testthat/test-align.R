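# Mapper, SAM/BAM ingestion, insert model, pair classification.

test_that("exact reads map uniquely with no clipping", {
    gm <- makeToyGenome(c(chrA = 20000, chrB = 30000), seed = 21)
    seqs <- as.character(sequences(gm))
    reads <- Biostrings::DNAStringSet(c(
        "r1/1" = substr(seqs["chrA"], 5001, 5100),
        "r2/1" = substr(seqs["chrB"], 12001, 12100),
        "r3/1" = as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(substr(seqs["chrA"], 8001, 8100))))))
    aln <- builtinMap(list(read1 = reads), gm)
    expect_true(all(aln$mapped))
    expect_identical(aln$chrom, c("chrA", "chrB", "chrA"))
    expect_identical(aln$pos, c(5001, 12001, 8001))
    expect_identical(aln$strand, c("+", "+", "-"))
    expect_identical(aln$mapq, c(60, 60, 60))
    expect_identical(aln$clipLeft + aln$clipRight, c(0, 0, 0))
    expect_error(builtinMap(list(read1 = reads), GenomeModel(c(c1 = 10))),
                 "empty reference")
})

test_that("junction-straddling reads are clipped towards the junction", {
    gm <- makeToyGenome(c(chrA = 20000, chrB = 30000), seed = 22)
    seqs <- as.character(sequences(gm))
    # 60 bases of chrA ending at 10000 followed by 40 foreign bases
    straddle <- paste0(substr(seqs["chrA"], 9941, 10000),
                       substr(seqs["chrB"], 20001, 20040))
    aln <- builtinMap(list(read1 = Biostrings::DNAStringSet(
        c("s/1" = straddle))), gm)
    expect_true(aln$mapped)
    expect_identical(aln$chrom, "chrA")
    expect_identical(aln$pos, 9941)
    # the clip faces the junction (a base or two of the foreign tail
    # may coincidentally match the reference continuation)
    expect_gte(aln$clipRight, 36)
    expect_identical(aln$clipLeft, 0)
})

test_that("reads from unrelated sequence stay unmapped", {
    gm <- makeToyGenome(c(chrA = 20000), seed = 23)
    other <- makeToyGenome(c(chrZ = 20000), seed = 99)
    rd <- Biostrings::DNAStringSet(
        c("u/1" = substr(as.character(sequences(other))[1], 1, 100)))
    aln <- builtinMap(list(read1 = rd), gm)
    expect_false(aln$mapped)
    expect_identical(aln$mapq, 0)
})

test_that("repeated loci yield the tied-placement mapping quality", {
    base <- makeToyGenome(c(chrA = 5000), seed = 24)
    s <- as.character(sequences(base))[1]
    dup <- GenomeModel(sequences = Biostrings::DNAStringSet(
        c(chrA = paste0(s, s))))
    rd <- Biostrings::DNAStringSet(c("t/1" = substr(s, 2001, 2100)))
    aln <- builtinMap(list(read1 = rd), dup)
    expect_true(aln$mapped)
    expect_identical(aln$mapq, 3)
})

test_that("SAM round-trips through writer and reader", {
    gm <- toyGenome()
    ts <- applyJunctions(gm, list(Junction(Breakend("chrA", 20000, "F"),
                                           Breakend("chrB", 32000, "R"))))
    reads <- simulateReads(ts, SimulationConfig(seed = 25))
    aln <- builtinMap(reads, ts@genome)
    sam <- tempfile(fileext = ".sam")
    writeSam(aln, ts@genome, sam, seed = 25)
    back <- readAlignments(sam)
    expect_identical(nrow(back), nrow(aln))
    o1 <- order(aln$qname, aln$mate); o2 <- order(back$qname, back$mate)
    for (f in c("qname", "mate", "mapped", "chrom", "pos", "strand",
                "mapq", "clipLeft", "clipRight", "alignedLen", "seq")) {
        expect_equal(aln[[f]][o1], back[[f]][o2], label = f)
    }
    # and through BAM via samtools-backed conversion
    bam <- Rsamtools::asBam(sam, tempfile(), indexDestination = FALSE)
    fromBam <- readAlignments(bam)
    expect_identical(nrow(fromBam), nrow(aln))
    expect_setequal(fromBam$qname, aln$qname)
})

test_that("insert model uses the median and scaled MAD", {
    m <- estimateInsertModel(rep(300, 150), minPairs = 100)
    expect_identical(m@center, 300)
    expect_identical(m@spread, 0)
    m2 <- estimateInsertModel(rep(c(280, 290, 300, 310, 320), 30),
                              minPairs = 100)
    expect_identical(m2@center, 300)
    expect_equal(m2@spread, 14.826, tolerance = 1e-9)
    set.seed(31)
    m3 <- estimateInsertModel(rnorm(5000, 375, 35))
    expect_true(abs(m3@center - 375) < 2)
    expect_true(abs(m3@spread - 35) < 4)
    expect_true(m3@unimodal)
    expect_error(estimateInsertModel(rep(300, 50)), "at least 100")
})

mkPair <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                   mq1 = 60, mq2 = 60, len = 100) {
    data.frame(qname = "q", mapped1 = TRUE, chrom1 = chrom1, pos1 = pos1,
               end1 = pos1 + len - 1, strand1 = strand1, mapq1 = mq1,
               clipLeft1 = 0, clipRight1 = 0,
               mapped2 = TRUE, chrom2 = chrom2, pos2 = pos2,
               end2 = pos2 + len - 1, strand2 = strand2, mapq2 = mq2,
               clipLeft2 = 0, clipRight2 = 0,
               separation = ifelse(chrom1 == chrom2,
                                   max(pos1, pos2) + len - 1 -
                                       min(pos1, pos2) + 1, NA),
               stringsAsFactors = FALSE)
}

test_that("pair classes follow the stated criteria literally", {
    model <- new("InsertSizeModel", center = 300, spread = 30,
                 nPairs = 1000, unimodal = TRUE)
    cls <- function(p, ...) classifyPairs(p, model, ...)
    expect_identical(cls(mkPair("chr12", 100, "+", "chr21", 500, "-")),
                     "interchromosomal")
    # separation 450: |450 - 300| = 150 > 4 * 30
    p <- mkPair("chr1", 100, "+", "chr1", 451, "-", len = 100)
    p$separation <- 450
    expect_identical(cls(p), "discordant_distance")
    # separation 400 deviates by 100 <= 120: proper
    p$separation <- 400
    expect_identical(cls(p), "proper")
    # deviation exactly 4 SD is not discordant
    p$separation <- 420
    expect_identical(cls(p), "proper")
    p$separation <- 421
    expect_identical(cls(p), "discordant_distance")
    # same-strand mates are orientation-discordant
    p2 <- mkPair("chr1", 100, "+", "chr1", 300, "+")
    expect_identical(cls(p2), "discordant_orientation")
    # outward-facing (junction between reversed mates)
    p3 <- mkPair("chr1", 300, "+", "chr1", 100, "-")
    expect_identical(cls(p3), "discordant_orientation")
    # the mapping-quality threshold is strict: MQ 30 is excluded
    p4 <- mkPair("chr12", 100, "+", "chr21", 500, "-", mq1 = 30)
    expect_identical(cls(p4), "low_quality")
    p5 <- mkPair("chr12", 100, "+", "chr21", 500, "-", mq1 = 31)
    expect_identical(cls(p5), "interchromosomal")
})

test_that("every pair receives exactly one class", {
    gm <- toyGenome()
    ts <- applyJunctions(gm, list())
    reads <- simulateReads(ts, SimulationConfig(seed = 33))
    aln <- builtinMap(reads, ts@genome)
    pairs <- pairAlignments(aln)
    model <- estimateInsertModel(pairs)
    cls <- classifyPairs(pairs, model)
    expect_identical(length(cls), nrow(pairs))
    expect_true(all(cls %in% c("proper", "discordant_distance",
                               "discordant_orientation",
                               "interchromosomal", "low_quality")))
    # SV-free data: under 1% of informative pairs look discordant
    informative <- cls[cls != "low_quality"]
    expect_lt(mean(informative != "proper"), 0.01)
})
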