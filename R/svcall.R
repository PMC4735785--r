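#' @include AllClasses.R utils.R junctions.R align.R
NULL

#' Construct SvCallingParams
#'
#' Defaults encode the calling procedure's stated thresholds: mapping
#' quality strictly above 30, separation deviation above 4 standard
#' deviations, 750 bp breakpoint windows (allowed range 500-1000),
#' rejection of reads with 5 or more unaligned end bases, and support
#' requiring at least 2 bases crossing the junction. Cluster and
#' split-read support minima (3 pairs, 2 reads) are specificity choices
#' exposed as parameters.
#'
#' @param mqMin,kSd,windowBp,maxUnalignedEndBp,minCrossBases,
#'   minClusterPairs,minSupportReads,asmMinOverlap,asmMinIdentity,
#'   flankBp see [SvCallingParams-class].
#' @return an [SvCallingParams-class].
#' @export
SvCallingParams <- function(mqMin = 30, kSd = 4, windowBp = 750,
                            maxUnalignedEndBp = 5, minCrossBases = 2,
                            minClusterPairs = 3, minSupportReads = 2,
                            asmMinOverlap = 30, asmMinIdentity = 0.95,
                            flankBp = 300) {
    new("SvCallingParams", mqMin = mqMin, kSd = kSd, windowBp = windowBp,
        maxUnalignedEndBp = maxUnalignedEndBp,
        minCrossBases = minCrossBases, minClusterPairs = minClusterPairs,
        minSupportReads = minSupportReads, asmMinOverlap = asmMinOverlap,
        asmMinIdentity = asmMinIdentity, flankBp = flankBp)
}

setMethod("show", "SvCallingParams", function(object) {
    cat(sprintf(
        paste0("SvCallingParams mq>%d |sep-c|>%gSD window=%dbp ",
               "unalignedEnds<%d cross>=%d clusterPairs>=%d ",
               "support>=%d\n"),
        as.integer(object@mqMin), object@kSd, as.integer(object@windowBp),
        as.integer(object@maxUnalignedEndBp),
        as.integer(object@minCrossBases),
        as.integer(object@minClusterPairs),
        as.integer(object@minSupportReads)))
})

# ---------------------------------------------------------------------
# Discordant-pair clustering
# ---------------------------------------------------------------------

# split sorted positions into runs with adjacent gaps <= linkGap
linkRuns <- function(pos, linkGap) {
    o <- order(pos)
    gaps <- diff(pos[o])
    grp <- cumsum(c(1, gaps > linkGap))
    split(o, grp)
}

#' Cluster discordant and inter-chromosomal read pairs
#'
#' Single-linkage grouping of SV-evidence pairs by (ordered chromosome
#' pair, orientation class), linking pairs whose footprints on both
#' sides are within `center + 3 * spread` of each other. Clusters with
#' fewer than `minClusterPairs` members are dropped. Predicted
#' breakends are the innermost mate-end coordinates per strand: the
#' junction lies to the right of a `+` footprint (max end) and to the
#' left of a `-` footprint (min start). Breakend strand flags follow
#' the donor/acceptor semantics: on the donor (first) side `+` maps to
#' `F` and `-` to `R`; on the acceptor side `+` maps to `R` and `-` to
#' `F`.
#'
#' @param pairs data.frame from [pairAlignments()], with a `class`
#'   column from [classifyPairs()] (only `interchromosomal`,
#'   `discordant_distance`, `discordant_orientation` rows are used).
#' @param model an [InsertSizeModel-class].
#' @param params an [SvCallingParams-class].
#' @return list of clusters; each a list with `chrom1`, `chrom2`,
#'   `strand1`, `strand2` (breakend strand flags, side 1 = donor),
#'   `breakend1`, `breakend2` (predicted positions), `n` and `members`
#'   (row indices into `pairs`).
#' @export
clusterDiscordant <- function(pairs, model, params = SvCallingParams()) {
    evid <- pairs$class %in% c("interchromosomal", "discordant_distance",
                               "discordant_orientation") &
        pairs$mapq1 > params@mqMin & pairs$mapq2 > params@mqMin
    pr <- pairs[evid, , drop = FALSE]
    if (!nrow(pr)) return(list())
    rowIdx <- which(evid)

    # orient each pair so side 1 is the earlier chromosome
    flip <- chromRank(pr$chrom2) < chromRank(pr$chrom1) |
        (pr$chrom1 == pr$chrom2 & pr$pos2 < pr$pos1)
    side <- function(fld1, fld2)
        ifelse(flip, pr[[fld2]], pr[[fld1]])
    d <- data.frame(chrom1 = side("chrom1", "chrom2"),
                    pos1 = side("pos1", "pos2"),
                    end1 = side("end1", "end2"),
                    strand1 = side("strand1", "strand2"),
                    chrom2 = side("chrom2", "chrom1"),
                    pos2 = side("pos2", "pos1"),
                    end2 = side("end2", "end1"),
                    strand2 = side("strand2", "strand1"),
                    row = rowIdx, stringsAsFactors = FALSE)

    linkGap <- model@center + 3 * model@spread
    clusters <- list()
    for (key in unique(paste(d$chrom1, d$chrom2, d$strand1, d$strand2))) {
        g <- d[paste(d$chrom1, d$chrom2, d$strand1, d$strand2) == key, ,
               drop = FALSE]
        for (run1 in linkRuns(g$pos1, linkGap)) {
            g1 <- g[run1, , drop = FALSE]
            for (run2 in linkRuns(g1$pos2, linkGap)) {
                g2 <- g1[run2, , drop = FALSE]
                if (nrow(g2) < params@minClusterPairs) next
                be <- function(strand, pos, end)
                    if (strand == "+") max(end) else min(pos)
                clusters[[length(clusters) + 1]] <- list(
                    chrom1 = g2$chrom1[1], chrom2 = g2$chrom2[1],
                    strand1 = if (g2$strand1[1] == "+") "F" else "R",
                    strand2 = if (g2$strand2[1] == "+") "R" else "F",
                    breakend1 = be(g2$strand1[1], g2$pos1, g2$end1),
                    breakend2 = be(g2$strand2[1], g2$pos2, g2$end2),
                    n = nrow(g2), members = g2$row)
            }
        }
    }
    clusters
}

#' Extract reads around a predicted breakpoint
#'
#' Returns mapped reads overlapping `breakend +/- windowBp` plus
#' unmapped reads whose mates map inside that window.
#'
#' @param aln alignment data.frame.
#' @param chrom,breakend predicted breakpoint.
#' @param params an [SvCallingParams-class] (uses `windowBp`).
#' @param genome optional [GenomeModel-class] for bounds checking.
#' @return row indices into `aln`.
#' @export
extractWindowReads <- function(aln, chrom, breakend,
                               params = SvCallingParams(),
                               genome = NULL) {
    if (!is.null(genome)) {
        len <- chromLengths(genome)
        if (!(chrom %in% names(len)) || breakend < 1 ||
            breakend > len[[chrom]])
            stop("predicted breakend outside the reference")
    }
    w <- params@windowBp
    lo <- breakend - w; hi <- breakend + w
    endPos <- aln$pos + aln$alignedLen - 1
    inWin <- aln$mapped & aln$chrom == chrom & endPos >= lo &
        aln$pos <= hi
    inWin[is.na(inWin)] <- FALSE
    # unmapped mates of in-window reads
    key <- paste(aln$qname, aln$mate)
    mateKey <- paste(aln$qname, 3L - aln$mate)
    unmappedMate <- !aln$mapped & mateKey %in% key[inWin]
    which(inWin | unmappedMate)
}

# ---------------------------------------------------------------------
# Greedy overlap-consensus assembly
# ---------------------------------------------------------------------

# contig representation: list(counts = 4 x L matrix of base support)
seqToCounts <- function(codes) {
    L <- length(codes)
    m <- matrix(0, 4, L)
    ok <- !is.na(codes)
    m[cbind(codes[ok] + 1, which(ok))] <- 1
    m
}

countsConsensus <- function(m) {
    # majority base; ties broken towards the lexicographically smallest
    # base (A<C<G<T), making assembly deterministic
    apply(m, 2, which.max) - 1
}

# best overlap alignment between two code vectors at a fixed shift:
# returns matches / length of the overlap
overlapIdentity <- function(a, b, shift) {
    # b placed at offset `shift` relative to a (1-based: b[1] pairs a[shift])
    aIdx <- max(1, shift):min(length(a), shift + length(b) - 1)
    if (!length(aIdx)) return(c(0, 0))
    bIdx <- aIdx - shift + 1
    good <- !is.na(a[aIdx]) & !is.na(b[bIdx])
    c(sum(a[aIdx][good] == b[bIdx][good]), length(aIdx))
}

# hashed k-mer index of a code vector: environment kmer -> positions
kmerIndex <- function(codes, k = 21) {
    km <- kmerCodes(codes, k)
    okk <- which(!is.na(km))
    if (!length(okk)) return(new.env(parent = emptyenv()))
    list2env(split(okk, as.character(km[okk])),
             envir = new.env(parent = emptyenv()))
}

# candidate shifts of read b (given as fwd/rc code pair) against an
# indexed target; returns a two-column matrix (shift, ori) or NULL
candidateShifts <- function(bCodes, bRc, idx, k = 21) {
    pw <- 4^((k - 1):0)
    shifts <- numeric(0); oris <- numeric(0)
    for (ori in 1:2) {
        v <- if (ori == 1) bCodes else bRc
        L <- length(v)
        if (L < k) next
        nOff <- L - k + 1
        offs <- unique(c(seq(1, nOff, by = 5), nOff))
        for (off in offs) {
            q <- sum(v[off:(off + k - 1)] * pw)
            if (is.na(q)) next
            hit <- idx[[as.character(q)]]
            if (!is.null(hit)) {
                shifts <- c(shifts, hit - off + 1)
                oris <- c(oris, rep(ori, length(hit)))
            }
        }
    }
    if (!length(shifts)) return(NULL)
    keep <- !duplicated(shifts * 2 + oris)
    cbind(shift = shifts[keep], ori = oris[keep])
}

#' Greedy overlap-consensus contig assembly
#'
#' Deterministic greedy consensus assembly: the longest read (ties
#' broken lexicographically by sequence) seeds the contig; each round
#' merges the remaining read with the highest-scoring overlap against
#' the current consensus (overlap of at least `asmMinOverlap` bp at
#' `asmMinIdentity` identity or better, either orientation, candidate
#' placements found through shared 21-mers). Per-column base counts
#' accumulate across merges and the consensus takes the majority base
#' (ties towards the alphabetically first base). When reads fall into
#' disjoint groups the remaining groups are assembled the same way and
#' the longest contig is returned with `noAssembly = TRUE`.
#'
#' @param reads character vector of read sequences (any orientation).
#' @param params an [SvCallingParams-class].
#' @return list with `contig` (character), `nReads` merged into it and
#'   `noAssembly` flag.
#' @export
assembleContig <- function(reads, params = SvCallingParams()) {
    reads <- toupper(reads)
    reads <- reads[nchar(reads) > 0]
    if (!length(reads)) stop("no reads to assemble")
    k <- 21
    codesList <- lapply(reads, encodeDna)
    rcList <- lapply(codesList, revcompCodes)
    used <- logical(length(reads))

    assembleGroup <- function() {
        free <- which(!used)
        seed <- free[order(-nchar(reads[free]), reads[free])][1]
        used[seed] <<- TRUE
        counts <- seqToCounts(codesList[[seed]])
        consensus <- countsConsensus(counts)
        n <- 1
        repeat {
            free <- which(!used)
            if (!length(free)) break
            idx <- kmerIndex(consensus, k)
            best <- NULL; bestScore <- -Inf; bestSeq <- ""
            for (ri in free) {
                cs <- candidateShifts(codesList[[ri]], rcList[[ri]], idx, k)
                if (is.null(cs)) next
                for (ci in seq_len(nrow(cs))) {
                    b <- if (cs[ci, "ori"] == 1) codesList[[ri]]
                         else rcList[[ri]]
                    ov <- overlapIdentity(consensus, b, cs[ci, "shift"])
                    if (ov[2] < params@asmMinOverlap) next
                    if (ov[1] / ov[2] < params@asmMinIdentity) next
                    better <- ov[1] > bestScore ||
                        (ov[1] == bestScore && reads[ri] < bestSeq)
                    if (better) {
                        bestScore <- ov[1]
                        bestSeq <- reads[ri]
                        best <- list(ri = ri, ori = cs[ci, "ori"],
                                     shift = cs[ci, "shift"])
                    }
                }
            }
            if (is.null(best)) break
            b <- if (best$ori == 1) codesList[[best$ri]]
                 else rcList[[best$ri]]
            bCounts <- seqToCounts(b)
            startA <- 1; startB <- best$shift
            if (best$shift < 1) { startA <- 2 - best$shift; startB <- 1 }
            L <- max(startA + ncol(counts) - 1, startB + ncol(bCounts) - 1)
            m <- matrix(0, 4, L)
            m[, startA:(startA + ncol(counts) - 1)] <- counts
            rng <- startB:(startB + ncol(bCounts) - 1)
            m[, rng] <- m[, rng] + bCounts
            counts <- m
            consensus <- countsConsensus(counts)
            used[best$ri] <<- TRUE
            n <- n + 1
        }
        list(codes = consensus, n = n)
    }

    groups <- list()
    while (any(!used)) groups[[length(groups) + 1]] <- assembleGroup()
    ns <- vapply(groups, function(g) g$n, numeric(1))
    lens <- vapply(groups, function(g) length(g$codes), numeric(1))
    top <- groups[[order(-ns, -lens)[1]]]
    list(contig = decodeDna(top$codes), nReads = top$n,
         noAssembly = length(groups) > 1)
}

# ---------------------------------------------------------------------
# Junction resolution from a contig
# ---------------------------------------------------------------------

# locate an exact anchor (probe) in the genome, both strands; returns
# data.frame(chrom, start, strand) of hits
findAnchor <- function(probe, genome) {
    hits <- list()
    pat <- Biostrings::DNAString(probe)
    rcp <- Biostrings::reverseComplement(pat)
    for (ch in names(sequences(genome))) {
        subject <- sequences(genome)[[ch]]
        for (str in c("+", "-")) {
            m <- Biostrings::matchPattern(if (str == "+") pat else rcp,
                                          subject)
            if (length(m))
                hits[[length(hits) + 1]] <- data.frame(
                    chrom = ch, start = Biostrings::start(m),
                    end = Biostrings::end(m), strand = str)
        }
    }
    if (!length(hits)) return(NULL)
    do.call(rbind, hits)
}

# extend an anchored exact match in both directions; anchor occupies
# contig[cStart..cEnd] matching ref[rStart..rEnd] on `strand` of chrom.
# Returns the maximal exact match as contig interval + ref interval.
extendMatch <- function(contigCodes, genome, chrom, strand,
                        cStart, cEnd, rStart, rEnd) {
    refCodes <- encodeDna(as.character(sequences(genome)[[chrom]]))
    L <- length(refCodes); n <- length(contigCodes)
    if (strand == "+") {
        while (cStart > 1 && rStart > 1 &&
               !is.na(contigCodes[cStart - 1]) &&
               identical(contigCodes[cStart - 1], refCodes[rStart - 1])) {
            cStart <- cStart - 1; rStart <- rStart - 1
        }
        while (cEnd < n && rEnd < L &&
               !is.na(contigCodes[cEnd + 1]) &&
               identical(contigCodes[cEnd + 1], refCodes[rEnd + 1])) {
            cEnd <- cEnd + 1; rEnd <- rEnd + 1
        }
    } else {
        # contig matches the reverse complement: moving right in the
        # contig moves left in the reference
        while (cStart > 1 && rEnd < L &&
               !is.na(contigCodes[cStart - 1]) &&
               identical(contigCodes[cStart - 1], 3 - refCodes[rEnd + 1])) {
            cStart <- cStart - 1; rEnd <- rEnd + 1
        }
        while (cEnd < n && rStart > 1 &&
               !is.na(contigCodes[cEnd + 1]) &&
               identical(contigCodes[cEnd + 1], 3 - refCodes[rStart - 1])) {
            cEnd <- cEnd + 1; rStart <- rStart - 1
        }
    }
    list(cStart = cStart, cEnd = cEnd, rStart = rStart, rEnd = rEnd,
         strand = strand, chrom = chrom)
}

# find the maximal match anchored nearest the contig prefix (side =
# "prefix") or suffix (side = "suffix"): anchor probes are tried
# inward from the respective end until one has a (near-)unique exact
# genome hit, which is extended maximally in both directions. Isolated
# consensus errors truncate exact extension, so collinear follow-up
# matches (same chromosome, strand and diagonal) are merged into the
# running match; the first non-collinear match - the other side of the
# junction - stops the scan.
sideMatch <- function(contigCodes, contig, genome, side, probeLen = 25) {
    n <- nchar(contig)
    starts <- if (side == "prefix")
        seq(1, max(1, n - probeLen + 1), by = 5)
    else rev(seq(1, max(1, n - probeLen + 1), by = 5))
    diagOf <- function(m) if (m$strand == "+") m$rStart - m$cStart
                          else m$rEnd + m$cStart
    run <- NULL
    for (s in starts) {
        e <- min(n, s + probeLen - 1)
        if (e - s + 1 < probeLen) next
        if (!is.null(run)) {
            # only probe beyond the current match, towards the junction
            if (side == "prefix" && s <= run$cEnd - probeLen + 1) next
            if (side == "suffix" && s >= run$cStart) next
        }
        probe <- substr(contig, s, e)
        if (grepl("[^ACGT]", probe)) next
        hits <- findAnchor(probe, genome)
        if (is.null(hits) || nrow(hits) > 4) next
        best <- NULL
        for (h in seq_len(nrow(hits))) {
            m <- extendMatch(contigCodes, genome, hits$chrom[h],
                             hits$strand[h], s, e, hits$start[h],
                             hits$end[h])
            if (is.null(best) ||
                (m$cEnd - m$cStart) > (best$cEnd - best$cStart)) best <- m
        }
        if (is.null(run)) {
            run <- best
        } else if (identical(best$chrom, run$chrom) &&
                   identical(best$strand, run$strand) &&
                   abs(diagOf(best) - diagOf(run)) <= 2) {
            # collinear continuation across an isolated error
            if (side == "prefix") {
                run$cEnd <- max(run$cEnd, best$cEnd)
                if (run$strand == "+") run$rEnd <- max(run$rEnd, best$rEnd)
                else run$rStart <- min(run$rStart, best$rStart)
            } else {
                run$cStart <- min(run$cStart, best$cStart)
                if (run$strand == "+") run$rStart <- min(run$rStart,
                                                         best$rStart)
                else run$rEnd <- max(run$rEnd, best$rEnd)
            }
        } else {
            break                       # reached the other side
        }
        fullyLeft <- side == "prefix" && run$cEnd >= n - 2
        fullyRight <- side == "suffix" && run$cStart <= 3
        if (fullyLeft || fullyRight) break
    }
    run
}

#' Resolve a junction contig to base-pair precision
#'
#' Finds the maximal exact match of the contig's prefix to one
#' reference locus (either strand) and of its suffix to another. The
#' overlap of the two matches is the microhomology; a gap between them
#' is the untemplated inserted sequence. The breakpoint is reported at
#' the leftmost donor coordinate consistent with the homology, and
#' strand flags follow the donor/acceptor segment semantics. A contig
#' fully explained by a single locus yields a `no junction` result.
#'
#' @param contig character contig sequence (any orientation).
#' @param genome a [GenomeModel-class] with sequences.
#' @param params an [SvCallingParams-class].
#' @return list with `junction` (a canonical [Junction-class], or
#'   `NULL`), `zone` (`c(zs, ze)`: contig indices of the last
#'   unambiguously donor-side base and the first unambiguously
#'   acceptor-side base — the homology tract or inserted bases lie
#'   between), and `reason` (for `NULL` junctions).
#' @export
resolveJunction <- function(contig, genome, params = SvCallingParams()) {
    contig <- toupper(contig)
    n <- nchar(contig)
    if (n < 2 * params@minCrossBases + 20)
        stop("contig too short to resolve")
    codes <- encodeDna(contig)
    noJunction <- function(reason)
        list(junction = NULL, zone = c(NA_real_, NA_real_),
             reason = reason)
    pre <- sideMatch(codes, contig, genome, "prefix")
    if (is.null(pre)) return(noJunction("prefix unanchored"))
    if (pre$cStart <= 3 && pre$cEnd >= n - 2)
        return(noJunction("no junction (reference allele)"))
    suf <- sideMatch(codes, contig, genome, "suffix")
    if (is.null(suf)) return(noJunction("suffix unanchored"))
    # same maximal match (or same diagonal, split by a sequencing
    # error) on both sides: reference allele, not a junction
    diagOf <- function(m) if (m$strand == "+") m$rStart - m$cStart
                          else m$rEnd + m$cStart
    if (pre$chrom == suf$chrom && pre$strand == suf$strand &&
        abs(diagOf(pre) - diagOf(suf)) <= 5)
        return(noJunction("no junction (reference allele)"))
    t <- pre$cEnd; u <- suf$cStart
    if (u > t + 1 + 50)
        return(noJunction("matches too far apart"))
    h <- t - u + 1                      # >0 homology, <0 gap
    mh <- max(0, h)
    ins <- if (u > t + 1) substr(contig, t + 1, u - 1) else ""

    # donor side from the prefix match; the breakpoint is reported at
    # the leftmost donor coordinate consistent with the homology: a
    # forward donor is retracted by mh bases, a reverse donor is kept
    # fully extended (its coordinate is minimal there), and the
    # acceptor placement shifts correspondingly
    if (pre$strand == "+") {
        donorPos <- pre$rEnd - mh
        donorStrand <- "F"
        accShift <- 0
    } else {
        donorPos <- pre$rStart
        donorStrand <- "R"
        accShift <- mh
    }
    if (suf$strand == "+") {
        accPos <- suf$rStart + accShift
        accStrand <- "F"
    } else {
        accPos <- suf$rEnd - accShift
        accStrand <- "R"
    }
    raw <- Junction(Breakend(pre$chrom, donorPos, donorStrand),
                    Breakend(suf$chrom, accPos, accStrand),
                    microhomologyLen = mh, insertedSeq = ins)
    j <- canonicalJunction(raw)
    # the resolved placement is donor-minimal in the contig's own
    # orientation; mirroring into canonical form flips it to the
    # donor-maximal end of the homology interval exactly when the two
    # strand flags differ - slide it back to the leftmost-donor
    # convention
    mirrored <- !identical(donor(j)@chrom, donor(raw)@chrom) ||
        !identical(donor(j)@pos, donor(raw)@pos) ||
        !identical(donor(j)@strand, donor(raw)@strand)
    if (mirrored && mh > 0 &&
        donor(j)@strand != acceptor(j)@strand) {
        s <- if (donor(j)@strand == "F") -mh else mh
        j <- slidePlacement(j, s)
    }
    list(junction = j, zone = c(min(t, u - 1), max(t + 1, u)),
         reason = NA_character_)
}

# slide a junction placement by s bases (s > 0 assigns s more bases to
# the donor side); valid within the microhomology interval
slidePlacement <- function(j, s) {
    d <- donor(j); a <- acceptor(j)
    Junction(Breakend(d@chrom, d@pos + if (d@strand == "F") s else -s,
                      d@strand),
             Breakend(a@chrom, a@pos + if (a@strand == "F") s else -s,
                      a@strand),
             microhomologyLen = microhomologyLen(j),
             insertedSeq = insertedSeq(j),
             supportPairs = supportPairs(j),
             supportSplit = supportSplit(j))
}

# ---------------------------------------------------------------------
# Split-read support counting
# ---------------------------------------------------------------------

# align one read (both orientations) to a contig by shared 21-mers and
# pick the best diagonal; returns NULL or list(start, end, clipL,
# clipR) of the best local segment in contig/read coordinates
alignReadToContig <- function(readCodes, contigCodes, contigKmerTab, k = 21) {
    bestSeg <- NULL; bestScore <- -Inf; bestOri <- 1
    n <- length(contigCodes)
    for (ori in c(1, 2)) {
        v <- if (ori == 1) readCodes else revcompCodes(readCodes)
        L <- length(v)
        if (L < k) next
        offs <- unique(c(seq(1, L - k + 1, by = 8), L - k + 1))
        diags <- integer(0)
        for (off in offs) {
            q <- sum(v[off:(off + k - 1)] * 4^((k - 1):0))
            hit <- contigKmerTab[[as.character(q)]]
            if (!is.null(hit)) diags <- c(diags, hit - off + 1)
        }
        for (d in unique(diags)) {
            idx <- d:(d + L - 1)
            refWin <- rep(NA_real_, L)
            okIdx <- idx >= 1 & idx <= n
            refWin[okIdx] <- contigCodes[idx[okIdx]]
            seg <- bestSegment(refWin == v)
            if (seg[3] > bestScore) {
                bestScore <- seg[3]
                bestSeg <- list(readStart = seg[1], readEnd = seg[2],
                                contigStart = d + seg[1] - 1,
                                contigEnd = d + seg[2] - 1,
                                score = seg[3], L = L)
                bestOri <- ori
            }
        }
    }
    if (is.null(bestSeg) || bestScore < 20) return(NULL)
    bestSeg$ori <- bestOri
    bestSeg
}

#' Count split reads supporting a resolved junction
#'
#' A read supports the junction iff (i) it aligns to the contig across
#' the junction offset with at least `minCrossBases` bases beyond the
#' junction on both sides, (ii) the contig alignment leaves fewer than
#' `maxUnalignedEndBp` unaligned bases at each read end, and (iii) the
#' read is not fully explained by a single reference locus (its best
#' reference alignment has clipped bases, or it is unmapped).
#'
#' @param readSeqs character vector of read sequences.
#' @param refClipped logical per read: does the read's best reference
#'   alignment leave clipped bases (or is it unmapped)?
#' @param contig character contig.
#' @param zone `c(zs, ze)` junction zone in contig coordinates (from
#'   [resolveJunction()]).
#' @param params an [SvCallingParams-class].
#' @return list with `support` count, `rejected` named counts by
#'   reason (`insufficient_cross`, `unaligned_ends`,
#'   `reference_explained`, `no_contig_alignment`) and `crossed`, the
#'   number of reads whose contig alignment touches the junction zone
#'   (supports plus the first two rejection classes partition it, with
#'   `reference_explained`).
#' @export
countSupport <- function(readSeqs, refClipped, contig, zone,
                         params = SvCallingParams()) {
    contigCodes <- encodeDna(toupper(contig))
    k <- 21
    tab <- kmerIndex(contigCodes, k)
    zs <- zone[1]; ze <- zone[2]
    support <- 0
    rejected <- c(insufficient_cross = 0, unaligned_ends = 0,
                  reference_explained = 0, no_contig_alignment = 0)
    crossed <- 0
    for (i in seq_along(readSeqs)) {
        codes <- encodeDna(toupper(readSeqs[i]))
        al <- alignReadToContig(codes, contigCodes, tab, k)
        if (is.null(al)) {
            rejected["no_contig_alignment"] <-
                rejected["no_contig_alignment"] + 1
            next
        }
        spans <- al$contigStart <= zs && al$contigEnd >= ze
        if (!spans) next                 # flank read, not junction evidence
        crossed <- crossed + 1
        okCross <- al$contigStart <= zs - params@minCrossBases + 1 &&
            al$contigEnd >= ze + params@minCrossBases - 1
        if (!okCross) {
            rejected["insufficient_cross"] <-
                rejected["insufficient_cross"] + 1
            next
        }
        clipL <- al$readStart - 1
        clipR <- al$L - al$readEnd
        if (clipL >= params@maxUnalignedEndBp ||
            clipR >= params@maxUnalignedEndBp) {
            rejected["unaligned_ends"] <- rejected["unaligned_ends"] + 1
            next
        }
        if (!refClipped[i]) {
            rejected["reference_explained"] <-
                rejected["reference_explained"] + 1
            next
        }
        support <- support + 1
    }
    list(support = support, rejected = rejected, crossed = crossed)
}

# ---------------------------------------------------------------------
# Whole-sample calling
# ---------------------------------------------------------------------

#' Call junctions for one sample
#'
#' End-to-end composition: classify pairs against the insert-size
#' model, cluster SV-evidence pairs, extract window reads around each
#' predicted breakpoint, assemble the clipped/unmapped subset into a
#' junction contig, resolve it to base pairs, count split-read support
#' and emit junctions meeting `minSupportReads` with fused flanking
#' sequence attached.
#'
#' @param aln alignment data.frame (from [builtinMap()] or
#'   [readAlignments()]).
#' @param genome a [GenomeModel-class] with sequences.
#' @param params an [SvCallingParams-class].
#' @param sample sample identifier.
#' @param model optional pre-estimated [InsertSizeModel-class];
#'   estimated from the data when `NULL`.
#' @return a [SampleCallset-class].
#' @export
callSample <- function(aln, genome, params = SvCallingParams(),
                       sample = "sample", model = NULL) {
    if (!nrow(aln)) return(SampleCallset(sample))
    pairs <- pairAlignments(aln)
    if (is.null(model)) model <- estimateInsertModel(pairs)
    pairs$class <- classifyPairs(pairs, model, mqMin = params@mqMin,
                                 kSd = params@kSd)
    clusters <- clusterDiscordant(pairs, model, params)
    if (!length(clusters)) return(SampleCallset(sample))

    found <- list()
    for (cl in clusters) {
        widx <- union(
            extractWindowReads(aln, cl$chrom1, cl$breakend1, params,
                               genome),
            extractWindowReads(aln, cl$chrom2, cl$breakend2, params,
                               genome))
        if (!length(widx)) next
        w <- aln[widx, , drop = FALSE]
        # clipped reads consistent with this cluster's orientation
        # class: a breakend with segment ending at the junction on the
        # high-coordinate side (donor F, acceptor R) clips split reads
        # on their high side; the mirror cases clip on the low side
        clipSide <- function(role, strandFlag) {
            if ((role == "donor") == (strandFlag == "F")) "right"
            else "left"
        }
        famReads <- function(chrom, side) {
            w$mapped & !is.na(w$chrom) & w$chrom == chrom &
                (if (side == "right")
                     !is.na(w$clipRight) &
                         w$clipRight >= params@minCrossBases
                 else !is.na(w$clipLeft) &
                         w$clipLeft >= params@minCrossBases)
        }
        interesting <- !w$mapped |
            famReads(cl$chrom1, clipSide("donor", cl$strand1)) |
            famReads(cl$chrom2, clipSide("acceptor", cl$strand2))
        asmReads <- w$seq[interesting]
        if (length(asmReads) < 2) next
        asm <- assembleContig(asmReads, params)
        if (nchar(asm$contig) < 2 * params@minCrossBases + 20) next
        res <- tryCatch(resolveJunction(asm$contig, genome, params),
                        error = function(e) list(junction = NULL))
        if (is.null(res$junction)) next
        refClipped <- !w$mapped | w$clipLeft > 0 | w$clipRight > 0
        sup <- countSupport(w$seq, refClipped, asm$contig, res$zone,
                            params)
        if (sup$support < params@minSupportReads) next
        fl <- junctionSequence(res$junction, genome,
                               flankBp = params@flankBp)
        j <- Junction(donor(res$junction), acceptor(res$junction),
                      microhomologyLen = microhomologyLen(res$junction),
                      insertedSeq = insertedSeq(res$junction),
                      supportPairs = cl$n, supportSplit = sup$support,
                      flankSeq = fl$seq)
        found[[junctionKey(j)]] <- j
    }
    SampleCallset(sample, unname(found),
                  provenance = list(params = params,
                                    insertModel = model))
}
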