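#' @include AllClasses.R junctions.R
NULL

# ---------------------------------------------------------------------
# Fixture readers: tab-separated tables in the breakpoint-table dialect
# (thousands separators tolerated on read, never written).
# ---------------------------------------------------------------------

#' Read a junction table (breakpoint-table TSV dialect)
#'
#' Columns: `Sample`, `Left_chr`, `Left_str`, `Left_breakpoint`,
#' `Gene_left`, `Right_chr`, `Right_str`, `Right_breakpoint`,
#' `Gene_right`, `Mode`; extra columns are preserved. Thousands
#' separators in coordinates are stripped.
#'
#' @param path TSV file path.
#' @return data.frame with normalized columns `sample`, `left_chr`,
#'   `left_str`, `left_pos`, `gene_left`, `right_chr`, `right_str`,
#'   `right_pos`, `gene_right`, `mode` (plus any extras).
#' @export
readJunctionTable <- function(path) {
    tbl <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE,
                             colClasses = "character")
    need <- c("Sample", "Left_chr", "Left_str", "Left_breakpoint",
              "Gene_left", "Right_chr", "Right_str", "Right_breakpoint",
              "Gene_right", "Mode")
    miss <- setdiff(need, names(tbl))
    if (length(miss))
        stop("junction table missing columns: ",
             paste(miss, collapse = ", "))
    badStr <- !(tbl$Left_str %in% c("F", "R")) |
              !(tbl$Right_str %in% c("F", "R"))
    if (any(badStr))
        stop("malformed strand value in row(s): ",
             paste(which(badStr), collapse = ", "))
    out <- data.frame(
        sample = tbl$Sample,
        left_chr = tbl$Left_chr, left_str = tbl$Left_str,
        left_pos = stripCommas(tbl$Left_breakpoint),
        gene_left = tbl$Gene_left,
        right_chr = tbl$Right_chr, right_str = tbl$Right_str,
        right_pos = stripCommas(tbl$Right_breakpoint),
        gene_right = tbl$Gene_right,
        mode = tbl$Mode, stringsAsFactors = FALSE)
    extra <- setdiff(names(tbl), need)
    for (e in extra) out[[e]] <- tbl[[e]]
    out
}

#' Convert junction-table rows into per-sample callsets
#'
#' @param tbl data.frame from [readJunctionTable()].
#' @return named list of [SampleCallset-class], one per sample.
#' @export
asCallsets <- function(tbl) {
    out <- lapply(split(tbl, tbl$sample), function(d) {
        js <- lapply(seq_len(nrow(d)), function(i) {
            Junction(Breakend(d$left_chr[i], d$left_pos[i], d$left_str[i]),
                     Breakend(d$right_chr[i], d$right_pos[i],
                              d$right_str[i]))
        })
        SampleCallset(d$sample[1], js)
    })
    out[unique(tbl$sample)]
}

#' Read a patient table (clinical-table TSV dialect)
#'
#' Expected columns include `POND_number`, `Gender`, `Age_years`, `WBC`,
#' `Blast_ratio`, `Treatment_outcome` (`Alive`/`Relapse`) and
#' `Remission_time_days`. Relapse outcomes are interpreted as events at
#' the remission time; Alive outcomes as censoring times.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
readPatientTable <- function(path) {
    tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
    tbl$Remission_time_days <- stripCommas(tbl$Remission_time_days)
    if (any(tbl$Remission_time_days <= 0, na.rm = TRUE))
        stop("remission times must be positive")
    tbl
}

#' Read a diagnosis/relapse translocation comparison table
#' @param path TSV file path with columns `Patient`,
#'   `Translocation_diagnosis`, `Translocation_relapse` (patterns like
#'   `"t(12;21);t(5;12);t(5;21)"`).
#' @return data.frame.
#' @export
readRelapseTable <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Parse a translocation pattern string into chromosome pairs
#'
#' `"t(12;21);t(5;12)"` becomes `c("chr12|chr21", "chr5|chr12")`.
#' @param pattern pattern string.
#' @return character vector of `chrA|chrB` pair keys (natural order).
#' @export
parseTranslocationPattern <- function(pattern) {
    if (is.na(pattern) || !nzchar(pattern)) return(character(0))
    parts <- regmatches(pattern,
                        gregexpr("t\\(([0-9XY]+);([0-9XY]+)\\)", pattern))[[1]]
    vapply(parts, function(p) {
        ch <- paste0("chr", strsplit(gsub("t\\(|\\)", "", p), ";")[[1]])
        ch <- ch[order(chromRank(ch))]
        paste(ch, collapse = "|")
    }, character(1), USE.NAMES = FALSE)
}

# chromosome-pair key of one junction-table row
rowPairKey <- function(tbl) {
    mapply(function(c1, c2) {
        ch <- c(c1, c2)[order(chromRank(c(c1, c2)))]
        paste(ch, collapse = "|")
    }, tbl$left_chr, tbl$right_chr, USE.NAMES = FALSE)
}

# ---------------------------------------------------------------------
# Cohort statistics
# ---------------------------------------------------------------------

#' Census of translocation orientation types across patients
#'
#' Restricted to junctions with both breakends on the primary pair
#' (regardless of whether a breakend lies inside the capture
#' intervals); counts patients, not rows: a patient contributes once to
#' each type it presents.
#'
#' @param tbl junction table from [readJunctionTable()].
#' @param primaryPair primary chromosome pair.
#' @return list with `counts` (named numeric over a-d) and `byPatient`
#'   (patient x type logical matrix).
#' @export
countTypes <- function(tbl, primaryPair = c("chr12", "chr21")) {
    patients <- unique(tbl$sample)
    types <- c("a", "b", "c", "d")
    m <- matrix(FALSE, length(patients), 4,
                dimnames = list(patients, types))
    if (nrow(tbl)) {
        for (i in seq_len(nrow(tbl))) {
            j <- Junction(Breakend(tbl$left_chr[i], tbl$left_pos[i],
                                   tbl$left_str[i]),
                          Breakend(tbl$right_chr[i], tbl$right_pos[i],
                                   tbl$right_str[i]))
            if (!isPrimaryPair(j, primaryPair)) next
            m[tbl$sample[i], classifyType(j, primaryPair)] <- TRUE
        }
    }
    list(counts = stats::setNames(as.numeric(colSums(m)), types),
         byPatient = m)
}

#' Identify patients with three-way translocations
#'
#' A patient is three-way iff any junction has a breakend on a
#' chromosome outside the primary pair; the partner is that chromosome.
#'
#' @param tbl junction table from [readJunctionTable()].
#' @param primaryPair primary chromosome pair.
#' @return named character vector: partner chromosome(s, collapsed with
#'   `,`) per three-way patient.
#' @export
findThreeWay <- function(tbl, primaryPair = c("chr12", "chr21")) {
    if (!nrow(tbl)) return(stats::setNames(character(0), character(0)))
    off <- mapply(function(c1, c2) {
        ch <- unique(c(c1, c2))
        paste(sort(ch[!(ch %in% primaryPair)]), collapse = ",")
    }, tbl$left_chr, tbl$right_chr, USE.NAMES = FALSE)
    keep <- nzchar(off)
    if (!any(keep)) return(stats::setNames(character(0), character(0)))
    agg <- tapply(off[keep], tbl$sample[keep], function(x)
        paste(unique(unlist(strsplit(x, ","))), collapse = ","))
    stats::setNames(as.character(agg), names(agg))
}

#' Lengths of capture target regions
#'
#' @param targets `GRanges` of 1-based inclusive intervals, or a
#'   data.frame with `chrom`, `start`, `end`.
#' @return list with `perRegion` (data.frame chrom/start/end/bp) and
#'   `totalBp`, `totalKbp` (nearest-integer kbp).
#' @export
regionStats <- function(targets) {
    if (is(targets, "GRanges")) {
        df <- data.frame(chrom = as.character(
                             GenomicRanges::seqnames(targets)),
                         start = GenomicRanges::start(targets),
                         end = GenomicRanges::end(targets))
    } else df <- targets
    if (any(df$start > df$end)) stop("interval start > end")
    df$bp <- df$end - df$start + 1
    list(perRegion = df, totalBp = sum(df$bp),
         totalKbp = roundHalfUp(sum(df$bp) / 1000, 0))
}

#' Breakpoint offsets from the start of their capture region
#'
#' @param tbl junction table from [readJunctionTable()].
#' @param targets capture regions as a `GRanges` with a `name` metadata
#'   column (gene label) or data.frame with `chrom`, `start`, `end`,
#'   `name`.
#' @return data.frame, one row per breakend: `sample`, `chrom`, `pos`,
#'   `region`, `offset` (1-based from region start; `NA` with
#'   `inRegion = FALSE` when the breakend falls outside every region).
#' @export
breakpointOffsets <- function(tbl, targets) {
    if (is(targets, "GRanges")) {
        tg <- data.frame(chrom = as.character(
                             GenomicRanges::seqnames(targets)),
                         start = GenomicRanges::start(targets),
                         end = GenomicRanges::end(targets),
                         name = if (!is.null(S4Vectors::mcols(targets)$name))
                             S4Vectors::mcols(targets)$name
                         else as.character(seq_along(targets)))
    } else tg <- targets
    ends <- rbind(
        data.frame(sample = tbl$sample, chrom = tbl$left_chr,
                   pos = tbl$left_pos),
        data.frame(sample = tbl$sample, chrom = tbl$right_chr,
                   pos = tbl$right_pos))
    ends$region <- NA_character_
    ends$offset <- NA_real_
    for (k in seq_len(nrow(tg))) {
        hit <- ends$chrom == tg$chrom[k] & ends$pos >= tg$start[k] &
            ends$pos <= tg$end[k]
        ends$region[hit] <- tg$name[k]
        ends$offset[hit] <- ends$pos[hit] - tg$start[k] + 1
    }
    ends$inRegion <- !is.na(ends$region)
    ends
}

#' Cohort clinical summary
#'
#' @param patients data.frame from [readPatientTable()].
#' @return list: `n`, `meanAge` (half-up, one decimal), `sexCounts`,
#'   `relapseCount`, `excludedMissingAge`.
#' @export
cohortSummary <- function(patients) {
    age <- suppressWarnings(as.numeric(patients$Age_years))
    excl <- sum(is.na(age))
    if (excl) warning(sprintf("%d row(s) excluded for missing age", excl))
    list(n = nrow(patients),
         meanAge = roundHalfUp(mean(age, na.rm = TRUE), 1),
         sexCounts = table(patients$Gender),
         relapseCount = sum(patients$Treatment_outcome == "Relapse"),
         excludedMissingAge = excl)
}

# ---------------------------------------------------------------------
# Survival analysis, from first principles
# ---------------------------------------------------------------------

#' Two-group log-rank test with Kaplan-Meier curves
#'
#' Computes the standard two-group log-rank statistic from first
#' principles: at each distinct event time the observed events in group
#' 1 are compared with the expectation under the hypergeometric null
#' (`E = d * n1 / n`), with variance
#' `V = d (n - d) n1 n2 / (n^2 (n - 1))`; the chi-square statistic
#' `(O - E)^2 / V` is referred to a chi-square distribution with 1 df.
#' Kaplan-Meier step functions are returned per group.
#'
#' @param time numeric follow-up times (days).
#' @param event logical/0-1 event indicator (relapse = 1, alive =
#'   censored).
#' @param group two-level factor or character group labels.
#' @return a [SurvivalResult-class].
#' @export
logrankTest <- function(time, event, group) {
    event <- as.numeric(event)
    group <- as.factor(group)
    if (nlevels(group) != 2) stop("exactly two groups required")
    if (any(table(group) == 0)) stop("a group has zero members")
    if (sum(event) == 0) stop("no events")

    g1 <- levels(group)[1]
    eventTimes <- sort(unique(time[event == 1]))
    O <- E <- V <- numeric(length(eventTimes))
    for (i in seq_along(eventTimes)) {
        t0 <- eventTimes[i]
        atRisk <- time >= t0
        n <- sum(atRisk)
        n1 <- sum(atRisk & group == g1)
        d <- sum(event == 1 & time == t0)
        d1 <- sum(event == 1 & time == t0 & group == g1)
        O[i] <- d1
        E[i] <- d * n1 / n
        V[i] <- if (n > 1) d * (n - d) / (n - 1) * n1 / n * (n - n1) / n
                else 0
    }
    chisq <- (sum(O) - sum(E))^2 / sum(V)
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)

    km <- lapply(levels(group), function(g) {
        tt <- time[group == g]; ee <- event[group == g]
        ts <- sort(unique(tt[ee == 1]))
        surv <- numeric(length(ts)); s <- 1
        nRisk <- nEvent <- numeric(length(ts))
        for (i in seq_along(ts)) {
            nRisk[i] <- sum(tt >= ts[i])
            nEvent[i] <- sum(ee == 1 & tt == ts[i])
            s <- s * (1 - nEvent[i] / nRisk[i])
            surv[i] <- s
        }
        data.frame(time = ts, nRisk = nRisk, nEvent = nEvent, surv = surv)
    })
    names(km) <- levels(group)
    new("SurvivalResult", groups = levels(group), km = km,
        table = data.frame(time = eventTimes, observed = O, expected = E,
                           variance = V),
        chisq = chisq, p = p)
}

setMethod("show", "SurvivalResult", function(object) {
    cat(sprintf("Two-group log-rank: chisq = %.3f (1 df), p = %.3g\n",
                object@chisq, object@p))
    cat(sprintf("  groups: %s\n", paste(object@groups, collapse = " vs ")))
})

#' One-sided exact hypergeometric tail probability
#'
#' Probability of observing at least `nEventsInGroup` of the `nEvents`
#' event-patients inside a group of size `nGroup` drawn from `nTotal`,
#' by exact enumeration of the hypergeometric tail terms.
#'
#' @param nTotal cohort size.
#' @param nGroup size of the group of interest.
#' @param nEvents number of event patients overall.
#' @param nEventsInGroup observed event patients inside the group.
#' @return the one-sided exact p-value.
#' @examples
#' hypergeomAssociation(26, 5, 4, 4)  # 5 / 14950
#' @export
hypergeomAssociation <- function(nTotal, nGroup, nEvents, nEventsInGroup) {
    if (nEventsInGroup > min(nGroup, nEvents) || nEvents > nTotal ||
        nGroup > nTotal || nEventsInGroup < 0)
        stop("inconsistent counts")
    ks <- nEventsInGroup:min(nGroup, nEvents)
    ks <- ks[nEvents - ks <= nTotal - nGroup]
    sum(choose(nGroup, ks) * choose(nTotal - nGroup, nEvents - ks)) /
        choose(nTotal, nEvents)
}
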