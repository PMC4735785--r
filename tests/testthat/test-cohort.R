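# Cohort statistics: table parsing, censuses, survival, exact test.

fixture <- function(name) system.file("extdata", name,
                                      package = "svfusion")

test_that("junction tables tolerate thousands separators and validate strands", {
    tbl <- readJunctionTable(fixture("table2_junctions.tsv"))
    expect_true(all(tbl$left_pos == round(tbl$left_pos)))
    # misplaced separators still parse to the intended coordinates
    expect_true(12028006 %in% tbl$left_pos)   # printed as 120,28,006
    expect_true(36265359 %in% tbl$right_pos)  # printed as 362,65,359
    bad <- tempfile(fileext = ".tsv")
    writeLines(paste(
        "Sample\tLeft_chr\tLeft_str\tLeft_breakpoint\tGene_left",
        "Right_chr\tRight_str\tRight_breakpoint\tGene_right\tMode",
        sep = "\t"), bad)
    cat("S1\tchr12\tX\t100\tETV6\tchr21\tR\t200\tRUNX1\tc\n",
        file = bad, append = TRUE)
    expect_error(readJunctionTable(bad), "row")
})

test_that("type census counts patients, not rows", {
    tbl <- data.frame(
        sample = c("p1", "p1", "p1", "p2"),
        left_chr = c("chr12", "chr12", "chr12", "chr12"),
        left_str = c("F", "F", "R", "R"),
        left_pos = c(100, 150, 200, 300),
        gene_left = "ETV6",
        right_chr = c("chr21", "chr21", "chr21", "chr21"),
        right_str = c("R", "R", "F", "R"),
        right_pos = c(1100, 1150, 1200, 1300),
        gene_right = "RUNX1", mode = "", stringsAsFactors = FALSE)
    ct <- countTypes(tbl)
    expect_identical(ct$counts, c(a = 0, b = 1, c = 1, d = 1))
    empty <- tbl[0, ]
    expect_identical(countTypes(empty)$counts, c(a = 0, b = 0, c = 0,
                                                 d = 0))
})

test_that("three-way detection keys on off-pair breakends only", {
    tbl <- data.frame(
        sample = c("p1", "p1", "p2"),
        left_chr = c("chr12", "chr15", "chr12"),
        left_str = "F", left_pos = c(100, 200, 8174744),
        gene_left = "g",
        right_chr = c("chr21", "chr21", "chr21"),
        right_str = "R", right_pos = c(1100, 1200, 1300),
        gene_right = "g", mode = "", stringsAsFactors = FALSE)
    tw <- findThreeWay(tbl)
    expect_identical(names(tw), "p1")
    expect_identical(unname(tw), "chr15")
    # a far-off chr12 breakend is still a chr12/chr21 junction
    expect_false("p2" %in% names(tw))
})

test_that("region arithmetic is 1-based inclusive", {
    st <- regionStats(data.frame(chrom = "chr21", start = 36259140,
                                 end = 36425395))
    expect_identical(st$perRegion$bp, 166256)
    expect_identical(
        regionStats(data.frame(chrom = "x", start = 5, end = 5))$totalBp, 1)
    expect_error(regionStats(data.frame(chrom = "x", start = 10, end = 2)),
                 "start > end")
})

test_that("breakpoint offsets are measured from the region start", {
    targets <- data.frame(chrom = c("chr12", "chr21"),
                          start = c(12022748, 36259140),
                          end = c(12037521, 36425395),
                          name = c("ETV6", "RUNX1"))
    tbl <- data.frame(sample = "p", left_chr = "chr12",
                      left_str = "F", left_pos = 12035255,
                      gene_left = "ETV6", right_chr = "chr21",
                      right_str = "F", right_pos = 37500446,
                      gene_right = "x", mode = "",
                      stringsAsFactors = FALSE)
    off <- breakpointOffsets(tbl, targets)
    expect_identical(off$offset[off$chrom == "chr12"], 12508)
    expect_false(off$inRegion[off$chrom == "chr21"])
    # region start maps to offset 1
    tbl$left_pos <- 12022748
    off <- breakpointOffsets(tbl, targets)
    expect_identical(off$offset[off$chrom == "chr12"], 1)
})

test_that("cohort summary rounds the mean age half-up", {
    pt <- data.frame(POND_number = "p", Gender = "Male", Age_years = 7,
                     Treatment_outcome = "Alive",
                     Remission_time_days = 100)
    expect_identical(cohortSummary(pt)$meanAge, 7)
    pt2 <- rbind(pt, within(pt, Age_years <- NA))
    expect_warning(s <- cohortSummary(pt2), "missing age")
    expect_identical(s$excludedMissingAge, 1L)
    # half-up at one decimal
    expect_identical(svfusion:::roundHalfUp(5.05, 1), 5.1)
})

test_that("log-rank statistic matches a first-principles hand computation", {
    pat <- readPatientTable(fixture("table1_patients.tsv"))
    tw <- findThreeWay(readJunctionTable(fixture("table2_junctions.tsv")))
    grp <- factor(ifelse(pat$POND_number %in% names(tw),
                         "three_way", "two_way"),
                  levels = c("three_way", "two_way"))
    res <- logrankTest(pat$Remission_time_days,
                       pat$Treatment_outcome == "Relapse", grp)
    # observed/expected/variance at the four event times, computed by
    # hand from the at-risk sets: t=428 (n1=4, n=20), t=546 (3, 16),
    # t=1297 (2, 9), t=1319 (1, 7), all events in group 1
    E <- 4 / 20 + 3 / 16 + 2 / 9 + 1 / 7
    V <- 4 * 16 / 400 + 3 * 13 / 256 + 2 * 7 / 81 + 1 * 6 / 49
    chi <- (4 - E)^2 / V
    expect_equal(res@chisq, chi, tolerance = 1e-12)
    expect_equal(res@p, pchisq(chi, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
    # swapping group labels leaves the statistic unchanged
    grp2 <- factor(as.character(grp), levels = rev(levels(grp)))
    expect_equal(logrankTest(pat$Remission_time_days,
                             pat$Treatment_outcome == "Relapse",
                             grp2)@chisq, res@chisq)
    # independent route: the survival package's score test
    if (requireNamespace("survival", quietly = TRUE)) {
        sd <- survival::survdiff(
            survival::Surv(pat$Remission_time_days,
                           pat$Treatment_outcome == "Relapse") ~ grp)
        expect_equal(res@chisq, sd$chisq, tolerance = 1e-8)
    }
    # Kaplan-Meier curves are proper survival functions
    for (km in res@km) {
        expect_true(all(km$surv >= 0 & km$surv <= 1))
        expect_true(all(diff(km$surv) <= 0))
    }
})

test_that("degenerate survival inputs raise errors", {
    expect_error(logrankTest(c(10, 20), c(0, 0), c("a", "b")),
                 "no events")
    expect_error(logrankTest(c(10, 20), c(1, 0), c("a", "a")),
                 "two groups")
})

test_that("exact hypergeometric tail equals brute-force enumeration", {
    # brute force over all subsets for small cohorts
    bruteForce <- function(nTotal, nGroup, nEvents, kObs) {
        subsets <- utils::combn(nTotal, nEvents)
        inGroup <- colSums(subsets <= nGroup)   # group = first nGroup ids
        mean(inGroup >= kObs)
    }
    set.seed(9)
    for (i in 1:20) {
        nTotal <- sample(4:12, 1)
        nGroup <- sample(1:nTotal, 1)
        nEvents <- sample(1:nTotal, 1)
        kObs <- sample(0:min(nGroup, nEvents), 1)
        if (nEvents - kObs > nTotal - nGroup) next
        expect_equal(hypergeomAssociation(nTotal, nGroup, nEvents, kObs),
                     bruteForce(nTotal, nGroup, nEvents, kObs),
                     tolerance = 1e-12)
    }
    # cross-check against the hypergeometric distribution function
    expect_equal(hypergeomAssociation(26, 5, 4, 4),
                 phyper(3, 5, 21, 4, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_identical(hypergeomAssociation(10, 10, 3, 3), 1)
    expect_error(hypergeomAssociation(10, 4, 3, 4), "inconsistent")
})
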