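# The caller: clustering, windows, assembly, resolution, support.

test_that("discordant clusters form around a junction and honour minima", {
    gm <- toyGenome()
    ts <- applyJunctions(gm, list(Junction(Breakend("chrA", 20000, "F"),
                                           Breakend("chrB", 32000, "R"))))
    reads <- simulateReads(ts, SimulationConfig(seed = 41))
    aln <- builtinMap(reads, ts@genome)
    pairs <- pairAlignments(aln)
    model <- estimateInsertModel(pairs)
    pairs$class <- classifyPairs(pairs, model)
    cl <- clusterDiscordant(pairs, model)
    expect_length(cl, 1)
    expect_identical(cl[[1]]$chrom1, "chrA")
    expect_identical(cl[[1]]$strand1, "F")
    expect_identical(cl[[1]]$strand2, "R")
    # innermost coordinates sit within one insert length of the truth
    expect_lt(abs(cl[[1]]$breakend1 - 20000), 500)
    expect_lt(abs(cl[[1]]$breakend2 - 32000), 500)
    # too few members: no cluster
    few <- pairs[pairs$class == "interchromosomal", ][1:2, ]
    few$class <- "interchromosomal"
    expect_length(clusterDiscordant(few, model), 0)
})

test_that("well-separated junctions produce separate clusters", {
    gm <- makeToyGenome(
        c(chrA = 80000, chrB = 80000),
        centromeres = list(chrA = c(70000, 71000), chrB = c(1000, 2000)),
        targetRegions = data.frame(chrom = c("chrA", "chrA"),
                                   start = c(9000, 59000),
                                   end = c(12000, 62000)),
        seed = 44)
    ts <- applyJunctions(gm, list(
        Junction(Breakend("chrA", 10000, "F"), Breakend("chrB", 30000, "R")),
        Junction(Breakend("chrA", 60000, "F"), Breakend("chrB", 31000, "R"))))
    reads <- simulateReads(ts, SimulationConfig(seed = 44))
    aln <- builtinMap(reads, ts@genome)
    pairs <- pairAlignments(aln)
    model <- estimateInsertModel(pairs)
    pairs$class <- classifyPairs(pairs, model)
    cl <- clusterDiscordant(pairs, model)
    expect_length(cl, 2)
})

test_that("window extraction applies the stated boundaries", {
    aln <- data.frame(
        qname = c("a", "b", "c", "d"), mate = 1L,
        mapped = c(TRUE, TRUE, TRUE, FALSE),
        chrom = c("chrA", "chrA", "chrA", NA),
        pos = c(10750, 10751, 9150, NA),
        strand = c("+", "+", "+", NA), mapq = 60,
        clipLeft = 0, clipRight = 0,
        alignedLen = c(100, 100, 100, 0),
        seq = "A", stringsAsFactors = FALSE)
    p <- SvCallingParams(windowBp = 750)
    # breakend 10000: window [9250, 10750]
    idx <- extractWindowReads(aln, "chrA", 10000, p)
    expect_true(1 %in% idx)      # starts exactly at the window edge
    expect_false(2 %in% idx)     # one base past the edge
    expect_false(3 %in% idx)     # ends at 9249, one base short
    # unmapped mate of an in-window read is pulled in
    aln2 <- aln
    aln2$qname <- c("a", "b", "c", "a")
    aln2$mate <- c(1L, 1L, 1L, 2L)
    idx2 <- extractWindowReads(aln2, "chrA", 10000, p)
    expect_true(4 %in% idx2)
    gm <- GenomeModel(c(chrA = 20000))
    expect_error(extractWindowReads(aln, "chrA", 30000, p, gm),
                 "outside the reference")
    expect_error(SvCallingParams(windowBp = 400), "windowBp")
})

test_that("greedy assembly reconstructs a tiled junction sequence", {
    gm <- toyGenome()
    ts <- applyJunctions(gm, list(Junction(Breakend("chrA", 20000, "F"),
                                           Breakend("chrB", 32000, "R"))))
    der <- as.character(ts@derivatives[[1]])
    # error-free 100-mers tiling 400 bp around the junction every 20 bp
    starts <- seq(19801, 20101, by = 20)
    tiles <- substring(der, starts, starts + 99)
    asm <- assembleContig(tiles)
    expect_false(asm$noAssembly)
    expect_equal(asm$nReads, length(tiles))
    expect_true(grepl(asm$contig, der, fixed = TRUE) ||
                grepl(svfusion:::revcomp(asm$contig), der, fixed = TRUE))
    expect_true(nchar(asm$contig) >= 400)
    # two disjoint groups: longest contig wins, flagged
    far <- substring(der, c(1000, 1060, 1120), c(1099, 1159, 1219))
    asm2 <- assembleContig(c(tiles, far))
    expect_true(asm2$noAssembly)
    # duplicates collapse to the read itself
    asm3 <- assembleContig(rep(tiles[1], 5))
    expect_identical(asm3$contig, tiles[1])
    expect_error(assembleContig(character(0)), "no reads")
})

test_that("assembly tolerates scattered errors via majority consensus", {
    gm <- toyGenome()
    ts <- applyJunctions(gm, list(Junction(Breakend("chrA", 20000, "F"),
                                           Breakend("chrB", 32000, "R"))))
    der <- as.character(ts@derivatives[[1]])
    starts <- rep(seq(19801, 20101, by = 25), each = 3)
    tiles <- substring(der, starts, starts + 99)
    set.seed(5)
    mut <- function(s) {
        i <- sample.int(nchar(s), 1)
        substr(s, i, i) <- sample(c("A", "C", "G", "T"), 1)
        s
    }
    noisy <- vapply(tiles, mut, character(1), USE.NAMES = FALSE)
    asm <- assembleContig(noisy)
    expect_true(grepl(asm$contig, der, fixed = TRUE) ||
                grepl(svfusion:::revcomp(asm$contig), der, fixed = TRUE))
})

test_that("contigs resolve to base-pair-exact junctions", {
    gm <- toyGenome()
    seqs <- as.character(sequences(gm))
    # donor chrA forward prefix to 20000, acceptor chrB reverse
    contig <- paste0(substr(seqs["chrA"], 19851, 20000),
                     svfusion:::revcomp(substr(seqs["chrB"], 31851, 32000)))
    res <- resolveJunction(contig, gm)
    expect_false(is.null(res$junction))
    j <- res$junction
    expect_identical(donor(j)@chrom, "chrA")
    expect_identical(donor(j)@pos, 20000)
    expect_identical(donor(j)@strand, "F")
    expect_identical(acceptor(j)@chrom, "chrB")
    expect_identical(acceptor(j)@pos, 32000)
    expect_identical(acceptor(j)@strand, "R")
    expect_identical(microhomologyLen(j), 0)
    # the reverse complement of the contig resolves identically
    res2 <- resolveJunction(svfusion:::revcomp(contig), gm)
    expect_identical(svfusion:::junctionKey(res2$junction),
                     svfusion:::junctionKey(j))
    expect_identical(donor(res2$junction)@pos, 20000)
    # a pure reference substring is the reference allele
    refOnly <- substr(seqs["chrA"], 1000, 1400)
    expect_null(resolveJunction(refOnly, gm)$junction)
    expect_match(resolveJunction(refOnly, gm)$reason, "no junction")
    expect_error(resolveJunction("ACGTACGT", gm), "too short")
})

test_that("engineered microhomology and insertions are recovered", {
    gm <- toyGenome()
    j <- Junction(Breakend("chrA", 20000, "F"), Breakend("chrB", 32000, "R"))
    ts <- applyJunctions(gm, list(j), homologyLen = 4)
    der <- as.character(ts@derivatives[[1]])
    contig <- substr(der, 19851, 20150)
    res <- resolveJunction(contig, ts@genome)
    expect_gte(microhomologyLen(res$junction), 4)
    expect_true(matchesTruth(res$junction, junctions(ts)[[1]],
                             ts@genome))
    expect_identical(donor(res$junction)@pos, 20000)

    tsi <- applyJunctions(gm, list(j), insertionSeq = "GGTACC")
    deri <- as.character(tsi@derivatives[[1]])
    resi <- resolveJunction(substr(deri, 19851, 20156), tsi@genome)
    expect_identical(insertedSeq(resi$junction), "GGTACC")
    expect_identical(donor(resi$junction)@pos, 20000)
    expect_identical(acceptor(resi$junction)@pos, 32000)
})

test_that("split-read support applies the crossing and end rules", {
    gm <- toyGenome()
    seqs <- as.character(sequences(gm))
    contig <- paste0(substr(seqs["chrA"], 19801, 20000),
                     svfusion:::revcomp(substr(seqs["chrB"], 31801, 32000)))
    res <- resolveJunction(contig, gm)
    zone <- res$zone
    params <- SvCallingParams()
    readAt <- function(start, len) substr(contig, start, start + len - 1)
    # spans with exactly 2 bases beyond the junction on the far side
    r2 <- readAt(zone[2] + params@minCrossBases - 1 - 99, 100)
    out <- countSupport(r2, refClipped = TRUE, contig, zone, params)
    expect_identical(out$support, 1)
    # only 1 extra base: insufficient crossing
    r1 <- readAt(zone[2] + 1 - 100, 100)
    out <- countSupport(r1, refClipped = TRUE, contig, zone, params)
    expect_identical(out$support, 0)
    expect_identical(unname(out$rejected["insufficient_cross"]), 1)
    # 5 unaligned end bases: rejected; 4: accepted
    mid <- readAt(zone[1] - 49, 100)
    junk5 <- paste0("AAAAA", substr(mid, 6, 100))
    junk4 <- paste0(substr(mid, 1, 96), "AAAA")
    # ensure the junk actually mismatches the contig
    substrOK <- substr(contig, zone[1] - 49, zone[1] - 45) != "AAAAA"
    if (substrOK) {
        out5 <- countSupport(junk5, TRUE, contig, zone, params)
        expect_identical(unname(out5$rejected["unaligned_ends"]), 1)
    }
    # 4 mismatching end bases stay under the rejection bound
    out4 <- countSupport(junk4, TRUE, contig, zone, params)
    expect_identical(out4$support, 1)
    outOK <- countSupport(mid, TRUE, contig, zone, params)
    expect_identical(outOK$support, 1)
    # a fully reference-explained read is never support
    outRef <- countSupport(mid, FALSE, contig, zone, params)
    expect_identical(outRef$support, 0)
    expect_identical(unname(outRef$rejected["reference_explained"]), 1)
    # support + rejections partition the junction-crossing reads
    batch <- c(r2, r1, mid)
    outAll <- countSupport(batch, c(TRUE, TRUE, FALSE), contig, zone,
                           params)
    expect_identical(outAll$support +
                     sum(outAll$rejected[c("insufficient_cross",
                                           "unaligned_ends",
                                           "reference_explained")]),
                     outAll$crossed)
})

test_that("support thresholds act monotonically on callsets", {
    gm <- toyGenome()
    ts <- applyJunctions(gm, list(Junction(Breakend("chrA", 20000, "F"),
                                           Breakend("chrB", 32000, "R")),
                                  Junction(Breakend("chrA", 20001, "R"),
                                           Breakend("chrB", 32001, "F"))))
    reads <- simulateReads(ts, SimulationConfig(seed = 55))
    aln <- builtinMap(reads, ts@genome)
    loose <- callSample(aln, ts@genome, SvCallingParams(minSupportReads = 2))
    strict <- callSample(aln, ts@genome,
                         SvCallingParams(minSupportReads = 1e6))
    keys <- function(cs) vapply(junctions(cs), svfusion:::junctionKey,
                                character(1))
    expect_true(all(keys(strict) %in% keys(loose)))
    expect_length(junctions(strict), 0)
})
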