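#' @include AllClasses.R utils.R genome.R
NULL

# ---------------------------------------------------------------------
# Alignments are handled internally as a plain data.frame, one row per
# read: qname, mate (1/2), mapped, chrom, pos (1-based leftmost aligned
# base), strand (+/-), mapq, clipLeft, clipRight, alignedLen, seq (in
# alignment orientation, i.e. reverse-complemented for - strand, as in
# SAM).
# ---------------------------------------------------------------------

emptyAlignments <- function() {
    data.frame(qname = character(0), mate = integer(0),
               mapped = logical(0), chrom = character(0), pos = numeric(0),
               strand = character(0), mapq = numeric(0),
               clipLeft = numeric(0), clipRight = numeric(0),
               alignedLen = numeric(0), seq = character(0),
               stringsAsFactors = FALSE)
}

# best-scoring contiguous segment of a +1/-2 match score vector
# (ungapped local alignment along a fixed diagonal); returns
# c(start, end, score) in sequence coordinates, or score 0
bestSegment <- function(match) {
    s <- ifelse(is.na(match), -1000, ifelse(match, 1, -2))
    cs <- cumsum(s)
    pref <- c(0, cs[-length(cs)])
    pm <- cummin(pref)
    gain <- cs - pm
    j <- which.max(gain)
    if (gain[j] <= 0) return(c(0, 0, 0))
    i <- which(pref[seq_len(j)] == pm[j])[1]
    c(i, j, gain[j])
}

#' Minimal built-in read mapper
#'
#' Exact k-mer seeding followed by ungapped extension (best local
#' segment under +1 match / -2 mismatch scoring along the seeded
#' diagonal), over both strands. Mapping quality is 60 for a unique
#' best placement, 3 for tied placements, 0/unmapped when no seed hits
#' or the best score falls below `minScore`. Bases outside the best
#' local segment are reported as soft clips. Intended for toy
#' references (up to ~1 Mbp); externally aligned SAM/BAM is the
#' first-class input path for real data.
#'
#' @param reads list with `read1`, `read2` DNAStringSets (as from
#'   [simulateReads()] / [readFastqPair()]), or a single DNAStringSet.
#' @param genome a [GenomeModel-class] with sequences.
#' @param k seed length (default 21).
#' @param minScore minimum acceptable segment score (default 30).
#' @return alignment data.frame (see package internals): one row per
#'   read, unmapped reads flagged with `mapped = FALSE`.
#' @export
builtinMap <- function(reads, genome, k = 21, minScore = 30) {
    if (!length(sequences(genome))) stop("empty reference")
    if (is(reads, "DNAStringSet")) reads <- list(read1 = reads)
    reads <- Filter(function(x) is(x, "DNAStringSet"), reads)

    refChrom <- names(sequences(genome))
    refStr <- as.character(sequences(genome))
    sep <- strrep("N", k + 1)
    concat <- paste(refStr, collapse = sep)
    codes <- encodeDna(concat)
    chromStart <- cumsum(c(1, nchar(refStr) + k + 1))[seq_along(refStr)]
    chromEnd <- chromStart + nchar(refStr) - 1

    refKmers <- kmerCodes(codes, k)
    ok <- which(!is.na(refKmers))
    keys <- refKmers[ok]
    o <- order(keys)
    sk <- keys[o]; sp <- ok[o]

    nConcat <- length(codes)

    qname <- character(0); mateNo <- integer(0); seqChar <- character(0)
    for (m in seq_along(reads)) {
        rs <- reads[[m]]
        qname <- c(qname, sub("/[12]$", "", names(rs)))
        mateNo <- c(mateNo, ifelse(grepl("/2$", names(rs)), 2L,
                                   ifelse(grepl("/1$", names(rs)), 1L,
                                          as.integer(m))))
        seqChar <- c(seqChar, as.character(rs))
    }
    if (!length(qname)) return(emptyAlignments())
    nReads <- length(seqChar)

    # candidate (read, strand, diagonal) triples from batched k-mer
    # lookups: one findInterval pass per (strand, seed offset)
    lens <- nchar(seqChar)
    readCodes <- lapply(seqChar, encodeDna)
    rcCodes <- lapply(readCodes, revcompCodes)
    candRead <- integer(0); candDiag <- numeric(0); candRc <- logical(0)
    for (L in unique(lens)) {
        if (L < k) next
        grp <- which(lens == L)
        M <- do.call(rbind, readCodes[grp])
        RC <- do.call(rbind, rcCodes[grp])
        offs <- unique(pmax(1, pmin(L - k + 1,
                                    round(seq(1, L - k + 1,
                                              length.out = 4)))))
        pw <- 4^((k - 1):0)
        for (isRc in c(FALSE, TRUE)) {
            V <- if (isRc) RC else M
            for (off in offs) {
                q <- as.numeric(V[, off:(off + k - 1), drop = FALSE] %*% pw)
                okq <- which(!is.na(q))
                if (!length(okq)) next
                lo <- findInterval(q[okq] - 0.5, sk) + 1
                hi <- findInterval(q[okq], sk)
                nh <- pmax(0, hi - lo + 1)
                has <- which(nh > 0)
                if (!length(has)) next
                spIdx <- sequence(nh[has], from = lo[has])
                rd <- rep(grp[okq[has]], nh[has])
                candRead <- c(candRead, rd)
                candDiag <- c(candDiag, sp[spIdx] - off + 1)
                candRc <- c(candRc, rep(isRc, length(rd)))
            }
        }
    }

    mapped <- logical(nReads); chrom <- rep(NA_character_, nReads)
    pos <- rep(NA_real_, nReads); strand <- rep(NA_character_, nReads)
    mapq <- numeric(nReads); clipL <- rep(NA_real_, nReads)
    clipR <- rep(NA_real_, nReads); alignedLen <- numeric(nReads)
    outSeq <- seqChar

    if (length(candRead)) {
        key <- candDiag * 2 + candRc
        byRead <- split(key, candRead)
        for (rdName in names(byRead)) {
            rd <- as.integer(rdName)
            L <- lens[rd]
            votes <- sort(table(byRead[[rdName]]), decreasing = TRUE)
            best <- -Inf; second <- -Inf; bestInfo <- NULL
            for (ck in as.numeric(names(votes)[seq_len(min(4,
                                                   length(votes)))])) {
                isRc <- ck %% 2 == 1
                d <- (ck - isRc) / 2
                if (d < 1 - L || d > nConcat) next
                idx <- d:(d + L - 1)
                refWin <- rep(NA_real_, L)
                okIdx <- idx >= 1 & idx <= nConcat
                refWin[okIdx] <- codes[idx[okIdx]]
                v <- if (isRc) rcCodes[[rd]] else readCodes[[rd]]
                seg <- bestSegment(refWin == v)
                if (seg[3] > best) {
                    second <- best
                    best <- seg[3]
                    bestInfo <- list(d = d, isRc = isRc, i = seg[1],
                                     j = seg[2])
                } else if (seg[3] > second) second <- seg[3]
            }
            if (is.null(bestInfo) || best < minScore) next
            i <- bestInfo$i; j <- bestInfo$j
            concatPos <- bestInfo$d + i - 1
            ci <- findInterval(concatPos, chromStart)
            if (ci < 1 || concatPos + (j - i) > chromEnd[ci]) next
            mapped[rd] <- TRUE
            chrom[rd] <- refChrom[ci]
            pos[rd] <- concatPos - chromStart[ci] + 1
            strand[rd] <- if (bestInfo$isRc) "-" else "+"
            mapq[rd] <- if (second >= best) 3 else 60
            clipL[rd] <- i - 1
            clipR[rd] <- L - j
            alignedLen[rd] <- j - i + 1
        }
    }
    flipIdx <- which(mapped & strand == "-")
    if (length(flipIdx)) outSeq[flipIdx] <- revcomp(seqChar[flipIdx])
    data.frame(qname = qname, mate = mateNo, mapped = mapped,
               chrom = chrom, pos = pos, strand = strand, mapq = mapq,
               clipLeft = clipL, clipRight = clipR,
               alignedLen = alignedLen, seq = outSeq,
               stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------
# SAM/BAM I/O
# ---------------------------------------------------------------------

cigarClips <- function(cigar) {
    left <- right <- numeric(length(cigar))
    hasL <- grepl("^[0-9]+S", cigar)
    hasR <- grepl("[0-9]+S$", cigar)
    left[hasL] <- as.numeric(sub("^([0-9]+)S.*", "\\1", cigar[hasL]))
    right[hasR] <- as.numeric(sub(".*?([0-9]+)S$", "\\1", cigar[hasR]))
    cbind(left = left, right = right)
}

cigarRefSpan <- function(cigar) {
    vapply(cigar, function(cg) {
        if (cg == "*") return(0)
        ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
        n <- as.numeric(sub("[A-Z=]$", "", ops))
        op <- sub("^[0-9]+", "", ops)
        sum(n[op %in% c("M", "D", "N", "=", "X")])
    }, numeric(1), USE.NAMES = FALSE)
}

#' Write alignments as SAM
#'
#' @param aln alignment data.frame (from [builtinMap()] or
#'   [readAlignments()]).
#' @param genome a [GenomeModel-class] (for `@SQ` header lines).
#' @param path output path.
#' @param seed optional seed recorded as an `@CO` header comment.
#' @return invisibly, `path`.
#' @export
writeSam <- function(aln, genome, path, seed = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("@HD\tVN:1.6\tSO:unsorted", con)
    len <- chromLengths(genome)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(len), as.integer(len)),
               con)
    if (!is.null(seed))
        writeLines(sprintf("@CO\tseed=%d", as.integer(seed)), con)
    if (!nrow(aln)) return(invisible(path))
    byName <- split(seq_len(nrow(aln)), aln$qname)
    lines <- character(nrow(aln))
    li <- 0
    for (idx in byName) {
        for (r in idx) {
            row <- aln[r, ]
            mateRow <- aln[setdiff(idx, r), ][1, ]
            flag <- 0x1
            flag <- flag + if (row$mate == 1) 0x40 else 0x80
            if (!row$mapped) flag <- flag + 0x4
            if (isTRUE(row$strand == "-")) flag <- flag + 0x10
            hasMate <- length(idx) > 1 && !is.na(mateRow$qname)
            if (hasMate) {
                if (!mateRow$mapped) flag <- flag + 0x8
                else if (isTRUE(mateRow$strand == "-")) flag <- flag + 0x20
            }
            cigar <- if (!row$mapped) "*" else {
                paste0(if (row$clipLeft > 0) sprintf("%dS", as.integer(row$clipLeft)) else "",
                       sprintf("%dM", as.integer(row$alignedLen)),
                       if (row$clipRight > 0) sprintf("%dS", as.integer(row$clipRight)) else "")
            }
            rnext <- if (hasMate && mateRow$mapped) {
                if (row$mapped && identical(mateRow$chrom, row$chrom)) "="
                else mateRow$chrom
            } else "*"
            pnext <- if (hasMate && mateRow$mapped) mateRow$pos else 0
            li <- li + 1
            lines[li] <- paste(row$qname, flag,
                               if (row$mapped) row$chrom else "*",
                               if (row$mapped) as.integer(row$pos) else 0,
                               as.integer(row$mapq), cigar, rnext,
                               as.integer(pnext), 0, row$seq,
                               strrep("F", nchar(row$seq)), sep = "\t")
        }
    }
    writeLines(lines[seq_len(li)], con)
    invisible(path)
}

samFlagField <- function(flag, bit) bitwAnd(flag, bit) != 0

#' Read alignments from SAM or BAM
#'
#' Format is auto-detected (BAM via its gzip magic, else text SAM).
#'
#' @param path SAM or BAM file.
#' @return alignment data.frame.
#' @export
readAlignments <- function(path) {
    magic <- readBin(path, "raw", n = 2)
    isBam <- length(magic) == 2 && magic[1] == as.raw(0x1f) &&
        magic[2] == as.raw(0x8b)
    if (isBam) {
        b <- Rsamtools::scanBam(path)[[1]]
        df <- data.frame(qname = b$qname, flag = b$flag,
                         chrom = as.character(b$rname), pos = b$pos,
                         mapq = b$mapq,
                         cigar = ifelse(is.na(b$cigar), "*", b$cigar),
                         seq = as.character(b$seq),
                         stringsAsFactors = FALSE)
    } else {
        ln <- readLines(path)
        ln <- ln[!startsWith(ln, "@")]
        if (!length(ln)) return(emptyAlignments())
        f <- strsplit(ln, "\t")
        df <- data.frame(
            qname = vapply(f, `[`, character(1), 1),
            flag = as.integer(vapply(f, `[`, character(1), 2)),
            chrom = vapply(f, `[`, character(1), 3),
            pos = as.numeric(vapply(f, `[`, character(1), 4)),
            mapq = as.numeric(vapply(f, `[`, character(1), 5)),
            cigar = vapply(f, `[`, character(1), 6),
            seq = vapply(f, `[`, character(1), 10),
            stringsAsFactors = FALSE)
    }
    clips <- cigarClips(df$cigar)
    mapped <- !samFlagField(df$flag, 0x4) & df$chrom != "*" &
        !is.na(df$chrom)
    data.frame(
        qname = df$qname,
        mate = ifelse(samFlagField(df$flag, 0x80), 2L, 1L),
        mapped = mapped,
        chrom = ifelse(mapped, df$chrom, NA_character_),
        pos = ifelse(mapped, df$pos, NA_real_),
        strand = ifelse(mapped,
                        ifelse(samFlagField(df$flag, 0x10), "-", "+"),
                        NA_character_),
        mapq = ifelse(is.na(df$mapq), 0, df$mapq),
        clipLeft = ifelse(mapped, clips[, "left"], NA_real_),
        clipRight = ifelse(mapped, clips[, "right"], NA_real_),
        alignedLen = ifelse(mapped, cigarRefSpan(df$cigar), 0),
        seq = df$seq, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------
# Pairing, insert-size model, concordance classes
# ---------------------------------------------------------------------

#' Join mate rows into read pairs
#'
#' @param aln alignment data.frame.
#' @return data.frame, one row per read pair, with per-mate columns
#'   suffixed `1`/`2` and `separation` (outer span in bp: rightmost
#'   aligned base - leftmost aligned base + 1) for co-chromosomal
#'   mapped pairs.
#' @export
pairAlignments <- function(aln) {
    a1 <- aln[aln$mate == 1, ]
    a2 <- aln[aln$mate == 2, ]
    m <- match(a1$qname, a2$qname)
    keep <- !is.na(m)
    a1 <- a1[keep, ]; a2 <- a2[m[keep], ]
    end1 <- a1$pos + a1$alignedLen - 1
    end2 <- a2$pos + a2$alignedLen - 1
    sameChrom <- a1$mapped & a2$mapped & a1$chrom == a2$chrom
    sep <- ifelse(sameChrom,
                  pmax(end1, end2) - pmin(a1$pos, a2$pos) + 1, NA_real_)
    out <- data.frame(
        qname = a1$qname,
        mapped1 = a1$mapped, chrom1 = a1$chrom, pos1 = a1$pos,
        end1 = end1, strand1 = a1$strand, mapq1 = a1$mapq,
        clipLeft1 = a1$clipLeft, clipRight1 = a1$clipRight,
        mapped2 = a2$mapped, chrom2 = a2$chrom, pos2 = a2$pos,
        end2 = end2, strand2 = a2$strand, mapq2 = a2$mapq,
        clipLeft2 = a2$clipLeft, clipRight2 = a2$clipRight,
        separation = sep, stringsAsFactors = FALSE)
    out
}

#' Estimate the insert-size model from concordant pairs
#'
#' Center is the median outer-span separation of co-chromosomal
#' inward-facing FR pairs; spread is the robust SD `1.4826 * MAD`.
#' Unimodality is flagged by counting substantial modes of a coarse
#' histogram.
#'
#' @param pairs data.frame from [pairAlignments()], or a numeric vector
#'   of separations.
#' @param minPairs minimum number of usable pairs (default 100).
#' @return an [InsertSizeModel-class].
#' @export
estimateInsertModel <- function(pairs, minPairs = 100) {
    if (is.numeric(pairs)) {
        seps <- pairs
    } else {
        use <- pairs$mapped1 & pairs$mapped2 &
            !is.na(pairs$separation) & isInwardFR(pairs)
        seps <- pairs$separation[use]
    }
    if (length(seps) < minPairs)
        stop(sprintf(paste("only %d co-chromosomal FR pairs; at least %d",
                           "needed - provide more input"),
                     length(seps), minPairs))
    center <- stats::median(seps)
    spread <- stats::mad(seps)  # constant 1.4826 by default
    h <- graphics::hist(seps, breaks = max(10, min(25, length(seps) %/% 20)),
                        plot = FALSE)
    cnt <- h$counts
    n <- length(cnt)
    sm <- (c(cnt[1], cnt[-n]) + cnt + c(cnt[-1], cnt[n])) / 3
    # substantial local maxima count as distinct modes only when the
    # valley between them drops below half the lower peak; sampling
    # wiggle on a single hump does not
    maxima <- which(vapply(seq_len(n), function(i) {
        l <- if (i > 1) sm[i - 1] else 0
        r <- if (i < n) sm[i + 1] else 0
        sm[i] > l && sm[i] >= r && sm[i] >= 0.25 * max(sm)
    }, logical(1)))
    peaks <- if (length(maxima) <= 1) length(maxima) else {
        modes <- 1
        for (k in 2:length(maxima)) {
            valley <- min(sm[maxima[k - 1]:maxima[k]])
            if (valley < 0.5 * min(sm[maxima[k - 1]], sm[maxima[k]]))
                modes <- modes + 1
        }
        modes
    }
    new("InsertSizeModel", center = center, spread = spread,
        nPairs = length(seps), unimodal = peaks <= 1)
}

setMethod("show", "InsertSizeModel", function(object) {
    cat(sprintf(
        "InsertSizeModel center=%g bp spread=%.1f bp (n=%d, %s)\n",
        object@center, object@spread, as.integer(object@nPairs),
        if (object@unimodal) "unimodal" else "NOT unimodal"))
})

# inward-facing FR on the same chromosome: the + mate starts no later
# than the - mate
isInwardFR <- function(pairs) {
    same <- pairs$mapped1 & pairs$mapped2 &
        !is.na(pairs$chrom1) & !is.na(pairs$chrom2) &
        pairs$chrom1 == pairs$chrom2
    fr <- same & (pairs$strand1 != pairs$strand2)
    plusFirst <- ifelse(pairs$strand1 == "+",
                        pairs$pos1 <= pairs$pos2, pairs$pos2 <= pairs$pos1)
    fr & plusFirst
}

#' Classify read pairs against the insert-size model
#'
#' Classes, in precedence order: `low_quality` when either mate's
#' mapping quality is <= `mqMin` (the quality requirement is strict:
#' MQ must exceed `mqMin`) or a mate is unmapped; `interchromosomal`
#' when the mates map to different chromosomes; `discordant_orientation`
#' when not inward-facing FR; `discordant_distance` when the separation
#' deviates from the model center by more than `kSd` spreads (two-sided);
#' otherwise `proper`.
#'
#' @param pairs data.frame from [pairAlignments()].
#' @param model an [InsertSizeModel-class].
#' @param mqMin mapping-quality floor (default 30, strict).
#' @param kSd deviation multiplier (default 4).
#' @return character vector of classes, one per pair.
#' @export
classifyPairs <- function(pairs, model, mqMin = 30, kSd = 4) {
    n <- nrow(pairs)
    out <- character(n)
    lowq <- !pairs$mapped1 | !pairs$mapped2 |
        pairs$mapq1 <= mqMin | pairs$mapq2 <= mqMin
    inter <- !lowq & pairs$chrom1 != pairs$chrom2
    inward <- isInwardFR(pairs)
    badOri <- !lowq & !inter & !inward
    badDist <- !lowq & !inter & !badOri &
        abs(pairs$separation - model@center) > kSd * model@spread
    out[lowq] <- "low_quality"
    out[inter] <- "interchromosomal"
    out[badOri] <- "discordant_orientation"
    out[badDist] <- "discordant_distance"
    out[out == ""] <- "proper"
    out
}
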