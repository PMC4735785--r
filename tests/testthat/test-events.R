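# Event interpretation, FISH pattern prediction, clonal comparison.

pair <- c("chr12", "chr21")

test_that("junction sets are interpreted into the documented events", {
    # three-way: primary c plus two junctions sharing chr15
    threeWay <- list(
        Junction(Breakend("chr12", 12029886, "F"),
                 Breakend("chr21", 38264151, "R")),
        Junction(Breakend("chr15", 86092449, "F"),
                 Breakend("chr21", 36264161, "F")),
        Junction(Breakend("chr15", 86092248, "R"),
                 Breakend("chr12", 12029986, "F")))
    ev <- interpretEvents(threeWay, pair)
    expect_length(ev, 1)
    expect_identical(eventClass(ev[[1]]), "three_way")
    expect_identical(partnerChromosomes(ev[[1]]), "chr15")

    # reciprocal c+d at nearly the same breakpoints
    recip <- list(
        Junction(Breakend("chr12", 12029780, "F"),
                 Breakend("chr21", 36363476, "R")),
        Junction(Breakend("chr12", 12029781, "R"),
                 Breakend("chr21", 36363464, "F")))
    ev <- interpretEvents(recip, pair)
    expect_length(ev, 1)
    expect_identical(eventClass(ev[[1]]), "two_way_reciprocal")

    # joint breaks of both homologues: b + d at distinct loci
    homol <- list(
        Junction(Breakend("chr12", 12033450, "R"),
                 Breakend("chr21", 36266210, "F")),
        Junction(Breakend("chr12", 12029669, "R"),
                 Breakend("chr21", 36266328, "R")))
    ev <- interpretEvents(homol, pair)
    expect_length(ev, 1)
    expect_identical(eventClass(ev[[1]]), "homologous_joint")

    # a lone c junction is a simple two-way translocation
    ev <- interpretEvents(recip[1], pair)
    expect_identical(eventClass(ev[[1]]), "two_way_simple")

    expect_identical(interpretEvents(list(), pair), list())
})

fishSetup <- function() {
    gm <- GenomeModel(
        c(chrA = 50000, chrB = 60000),
        centromeres = GenomicRanges::GRanges(
            c("chrA", "chrB"), IRanges::IRanges(c(40000, 5000),
                                                c(41000, 6000))))
    panel <- FishProbePanel(data.frame(
        color = c("green", "red"), chrom = c("chrA", "chrB"),
        start = c(10000, 30000), end = c(14000, 34000)),
        minDetectableBp = 1000)
    events <- interpretEvents(list(
        Junction(Breakend("chrA", 20000, "F"),
                 Breakend("chrB", 32000, "R")),
        Junction(Breakend("chrA", 20001, "R"),
                 Breakend("chrB", 32001, "F"))),
        primaryPair = c("chrA", "chrB"), genome = gm)
    list(gm = gm, panel = panel, events = events)
}

test_that("FISH prediction matches the extra-signal probe patterns", {
    fs <- fishSetup()
    # fusion-negative cell: two green, two red
    neg <- predictFishPattern(list(), fs$gm, fs$panel)
    expect_identical(neg$counts, c(green = 2, red = 2, yellow = 0))
    # classic reciprocal fusion: one green, two red (one large, one
    # small), one colocalized yellow
    pos <- predictFishPattern(fs$events, fs$gm, fs$panel)
    expect_identical(pos$counts, c(green = 1, red = 2, yellow = 1))
    redBp <- sort(pos$detail$redBp[pos$detail$signal == "red"])
    expect_true(redBp[1] < redBp[2])   # one small and one large red
    # nothing detectable when fragments are below the threshold
    blind <- FishProbePanel(data.frame(
        color = c("green", "red"), chrom = c("chrA", "chrB"),
        start = c(10000, 30000), end = c(14000, 34000)),
        minDetectableBp = 1e7)
    none <- predictFishPattern(fs$events, fs$gm, blind)
    expect_identical(none$counts, c(green = 0, red = 0, yellow = 0))
})

test_that("probe base pairs are conserved across predicted signals", {
    fs <- fishSetup()
    for (evs in list(list(), fs$events)) {
        out <- predictFishPattern(evs, fs$gm, fs$panel)
        carried <- sum(out$detail$greenBp) + sum(out$detail$redBp) +
            sum(out$detail$undetectedBp)
        expect_identical(carried, 2 * (4001 + 4001))
    }
})

test_that("clonal comparison distinguishes identical, subset, disjoint", {
    mkSet <- function(id, pairsList) {
        js <- lapply(pairsList, function(p)
            Junction(Breakend(p[1], as.numeric(p[2]), "F"),
                     Breakend(p[3], as.numeric(p[4]), "R")))
        SampleCallset(id, js)
    }
    dx <- mkSet("dx", list(c("chr12", 100, "chr21", 200),
                           c("chr5", 300, "chr12", 400),
                           c("chr5", 500, "chr21", 600)))
    expect_identical(compareClones(dx, dx)$relation, "identical")

    rl <- mkSet("rl", list(c("chr12", 100, "chr21", 200)))
    cmp <- compareClones(dx, rl)
    expect_identical(cmp$relation, "shared_subset")
    expect_length(cmp$lost, 2)
    expect_length(cmp$gained, 0)
    expect_true(cmp$coordinateOnly)   # no flank sequences attached

    none <- SampleCallset("none")
    expect_identical(compareClones(rl, none)$relation, "disjoint")
    # identical/disjoint verdicts are symmetric
    expect_identical(compareClones(none, rl)$relation, "disjoint")
    expect_identical(compareClones(rl, rl)$relation, "identical")
})

test_that("flank sequences sharpen clone identity", {
    j1 <- Junction(Breakend("chr12", 100, "F"), Breakend("chr21", 200, "R"),
                   flankSeq = strrep("ACGT", 50))
    j2 <- Junction(Breakend("chr12", 100, "F"), Breakend("chr21", 200, "R"),
                   flankSeq = strrep("TGCA", 50))
    a <- SampleCallset("a", list(j1))
    b <- SampleCallset("b", list(j2))
    same <- SampleCallset("c", list(j1))
    expect_identical(compareClones(a, same)$relation, "identical")
    expect_false(compareClones(a, same)$coordinateOnly)
    # same coordinates, different fused sequence: not the same clone
    expect_identical(compareClones(a, b)$relation, "disjoint")
})
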