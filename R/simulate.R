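#' @include AllClasses.R junctions.R derivatives.R
NULL

#' Construct a SimulationConfig
#'
#' @param seed integer RNG seed (mandatory).
#' @param readLen read length in bp (default 100).
#' @param insertMean,insertSd truncated-normal fragment length model
#'   (defaults 375 and 35 bp, matching a 350-400 bp size-selected
#'   library).
#' @param depth fold coverage over the target regions (default 30).
#' @param baseErrorRate per-base substitution probability (default
#'   0.001).
#' @param captureMargin capture slack around targets in bp (default 500).
#' @param offTargetRate fraction of pairs drawn genome-wide (default
#'   0.05).
#' @return a [SimulationConfig-class].
#' @export
SimulationConfig <- function(seed, readLen = 100, insertMean = 375,
                             insertSd = 35, depth = 30,
                             baseErrorRate = 0.001, captureMargin = 500,
                             offTargetRate = 0.05) {
    if (missing(seed)) stop("seed is mandatory")
    new("SimulationConfig", seed = as.numeric(seed),
        readLen = as.numeric(readLen), insertMean = as.numeric(insertMean),
        insertSd = as.numeric(insertSd), depth = as.numeric(depth),
        baseErrorRate = as.numeric(baseErrorRate),
        captureMargin = as.numeric(captureMargin),
        offTargetRate = as.numeric(offTargetRate))
}

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(
        "SimulationConfig seed=%d read=%dbp insert=N(%g,%g) depth=%gx\n",
        as.integer(object@seed), as.integer(object@readLen),
        object@insertMean, object@insertSd, object@depth))
})

# replace genome bases (1-based inclusive) on one chromosome
editGenomeBases <- function(genome, chrom, start, replacement) {
    seqs <- sequences(genome)
    s <- as.character(seqs[[chrom]])
    substr(s, start, start + nchar(replacement) - 1) <- replacement
    seqs[[chrom]] <- Biostrings::DNAString(s)
    methods::initialize(genome, sequences = seqs)
}

#' Apply junction specifications to a genome, producing a truth set
#'
#' Builds one derivative chromosome per junction following the strand
#' semantics of [buildDerivative()]: derivative sequence = donor segment
#' + inserted sequence + acceptor segment. A requested microhomology of
#' `h` bp is made real by copying the first `h` acceptor-segment bases
#' onto the donor's reference continuation beyond its breakpoint, so
#' that the junction is genuinely ambiguous over `h + 1` placements;
#' truth junctions record the leftmost-aligned donor coordinate.
#' Requesting both microhomology and an untemplated insertion is
#' contradictory (the inserted bases would separate the homologous
#' tracts) and raises an error.
#'
#' @param genome [GenomeModel-class] with sequences.
#' @param junctions list of [Junction-class] giving breakends (support
#'   and homology slots are ignored; homology/insertion come from the
#'   arguments below).
#' @param homologyLen microhomology bp per junction (recycled).
#' @param insertionSeq untemplated inserted sequence per junction
#'   (recycled; "" for none).
#' @return a [TruthSet-class]; its `genome` slot carries any base edits
#'   and must be used as the reference downstream.
#' @export
applyJunctions <- function(genome, junctions, homologyLen = 0,
                           insertionSeq = "") {
    if (!length(sequences(genome))) stop("genome carries no sequences")
    n <- length(junctions)
    homologyLen <- rep_len(homologyLen, n)
    insertionSeq <- rep_len(toupper(insertionSeq), n)
    if (any(homologyLen > 0 & nzchar(insertionSeq)))
        stop(paste("contradictory request: microhomology with an",
                   "untemplated insertion"))
    len <- chromLengths(genome)
    truth <- vector("list", n)
    segTables <- vector("list", n)

    # first pass: engineer homology by editing the donor continuation
    for (i in seq_len(n)) {
        h <- homologyLen[i]
        if (h == 0) next
        j <- junctions[[i]]
        d <- donor(j); a <- acceptor(j)
        accSeg <- breakendSegment(a, "acceptor", genome)
        accSeq <- derivativeSequence(accSeg, genome)
        bHead <- substr(accSeq, 1, h)
        if (d@strand == "F") {
            if (d@pos + h > len[[d@chrom]])
                stop("homology extends past chromosome end")
            genome <- editGenomeBases(genome, d@chrom, d@pos + 1, bHead)
        } else {
            if (d@pos - h < 1)
                stop("homology extends past chromosome start")
            genome <- editGenomeBases(genome, d@chrom, d@pos - h,
                                      revcomp(bHead))
        }
    }

    ders <- character(n)
    for (i in seq_len(n)) {
        j <- junctions[[i]]
        segs <- rbind(breakendSegment(donor(j), "donor", genome),
                      breakendSegment(acceptor(j), "acceptor", genome))
        ders[i] <- derivativeSequence(segs, genome,
                                      insertedSeq = insertionSeq[i])
        segTables[[i]] <- segs
        truth[[i]] <- Junction(donor(j), acceptor(j),
                               microhomologyLen = homologyLen[i],
                               insertedSeq = insertionSeq[i])
    }
    derSet <- Biostrings::DNAStringSet(ders)
    names(derSet) <- sprintf("der_%d_%s_%s", seq_len(n),
                             vapply(truth, function(j) donor(j)@chrom,
                                    character(1)),
                             vapply(truth, function(j) acceptor(j)@chrom,
                                    character(1)))
    new("TruthSet", junctions = truth, derivatives = derSet,
        derivativeSegments = segTables, genome = genome)
}

#' @rdname TruthSet-class
#' @param x a `TruthSet`.
#' @export
setMethod("junctions", "TruthSet", function(x) x@junctions)

setMethod("show", "TruthSet", function(object) {
    cat(sprintf("TruthSet with %d junction(s), %d derivative(s)\n",
                length(object@junctions), length(object@derivatives)))
})

# target intervals lifted into the coordinate space of one source
# sequence; native sources pass segments = whole chromosome
liftTargets <- function(segs, targets, margin) {
    if (!length(targets)) return(data.frame(start = numeric(0),
                                            end = numeric(0)))
    out <- list()
    offset <- 0
    for (i in seq_len(nrow(segs))) {
        segW <- segs$end[i] - segs$start[i] + 1
        tOnChrom <- targets[as.character(
            GenomicRanges::seqnames(targets)) == segs$chrom[i]]
        if (length(tOnChrom)) {
            s <- pmax(GenomicRanges::start(tOnChrom) - margin, segs$start[i])
            e <- pmin(GenomicRanges::end(tOnChrom) + margin, segs$end[i])
            keep <- s <= e
            s <- s[keep]; e <- e[keep]
            if (length(s)) {
                if (segs$orientation[i] == "fwd") {
                    ls <- offset + (s - segs$start[i]) + 1
                    le <- offset + (e - segs$start[i]) + 1
                } else {
                    ls <- offset + (segs$end[i] - e) + 1
                    le <- offset + (segs$end[i] - s) + 1
                }
                out[[length(out) + 1]] <- data.frame(start = ls, end = le)
            }
        }
        offset <- offset + segW
    }
    if (!length(out)) return(data.frame(start = numeric(0),
                                        end = numeric(0)))
    do.call(rbind, out)
}

#' Simulate capture-enriched paired-end reads
#'
#' Draws fragments from the sample's chromosomes (all native
#' chromosomes of the truth-set genome plus every derivative) with
#' lengths from a truncated normal (`N(insertMean, insertSd)`, floored
#' at `2 * readLen`), reads the two fragment ends in FR orientation,
#' and applies uniform substitution errors. Capture is emulated at the
#' pair level: on-target pairs are drawn only from fragment placements
#' overlapping a target region (lifted into derivative coordinates)
#' plus `captureMargin`, and `offTargetRate` of pairs are drawn
#' genome-wide. The on-target pair count is
#' `depth * targetBp / (2 * readLen)`.
#'
#' @param truthset a [TruthSet-class] (possibly junction-free for
#'   SV-negative controls).
#' @param config a [SimulationConfig-class].
#' @return list with `read1`, `read2` ([Biostrings::DNAStringSet-class]
#'   with mate names `<frag>/1`, `<frag>/2`) and `sources`
#'   (data.frame of true fragment origins).
#' @export
simulateReads <- function(truthset, config) {
    methods::validObject(config)
    genome <- truthset@genome
    if (!length(targetRegions(genome)))
        stop("genome has no target regions; capture simulation needs them")
    set.seed(as.integer(config@seed))
    readLen <- config@readLen

    srcSeqs <- c(as.character(sequences(genome)),
                 stats::setNames(as.character(truthset@derivatives),
                                 names(truthset@derivatives)))
    segsList <- c(lapply(names(sequences(genome)), function(ch)
                      data.frame(chrom = ch, start = 1,
                                 end = chromLengths(genome)[[ch]],
                                 orientation = "fwd")),
                  truthset@derivativeSegments)
    lifted <- lapply(segsList, liftTargets,
                     targets = targetRegions(genome),
                     margin = config@captureMargin)
    targetBpPerSrc <- vapply(lifted, function(d)
        sum(pmax(0, d$end - d$start + 1)), numeric(1))

    totalTargetBp <- sum(GenomicRanges::width(targetRegions(genome)))
    nOn <- round(config@depth * totalTargetBp / (2 * readLen))
    nOff <- round(nOn * config@offTargetRate /
                  max(1e-12, 1 - config@offTargetRate))
    if (nOn < 1) stop("depth yields zero read pairs")

    drawFragments <- function(nPairs, onTarget) {
        if (nPairs == 0) return(NULL)
        w <- if (onTarget) targetBpPerSrc
             else vapply(srcSeqs, nchar, numeric(1))
        if (sum(w) == 0) stop("no eligible source sequence")
        srcIdx <- sample(seq_along(srcSeqs), nPairs, replace = TRUE,
                         prob = w)
        fragLen <- pmax(2 * readLen,
                        round(stats::rnorm(nPairs, config@insertMean,
                                           config@insertSd)))
        starts <- numeric(nPairs)
        for (i in seq_len(nPairs)) {
            L <- nchar(srcSeqs[[srcIdx[i]]])
            fragLen[i] <- min(fragLen[i], L)
            maxStart <- L - fragLen[i] + 1
            if (onTarget) {
                tv <- lifted[[srcIdx[i]]]
                s <- pmax(1, tv$start - fragLen[i] + 1)
                e <- pmin(maxStart, tv$end)
                keep <- s <= e
                s <- s[keep]; e <- e[keep]
                if (!length(s)) { starts[i] <- NA; next }
                seg <- sample.int(length(s), 1, prob = e - s + 1)
                starts[i] <- s[seg] + sample.int(e[seg] - s[seg] + 1, 1) - 1
            } else {
                starts[i] <- sample.int(maxStart, 1)
            }
        }
        keep <- !is.na(starts)
        data.frame(src = srcIdx[keep], start = starts[keep],
                   len = fragLen[keep])
    }

    frags <- rbind(drawFragments(nOn, TRUE), drawFragments(nOff, FALSE))
    if (is.null(frags) || !nrow(frags)) stop("no fragments simulated")

    fwd <- substring(srcSeqs[frags$src], frags$start,
                     frags$start + readLen - 1)
    revPiece <- substring(srcSeqs[frags$src],
                          frags$start + frags$len - readLen,
                          frags$start + frags$len - 1)
    rev <- revcomp(revPiece)

    baseInts <- utf8ToInt("ACGT")
    addErrors <- function(seqs) {
        if (config@baseErrorRate <= 0) return(seqs)
        all <- utf8ToInt(paste(seqs, collapse = ""))
        hit <- which(stats::runif(length(all)) < config@baseErrorRate)
        if (length(hit)) {
            cur <- match(all[hit], baseInts)
            shift <- sample.int(3, length(hit), replace = TRUE)
            all[hit] <- baseInts[(cur - 1 + shift) %% 4 + 1]
        }
        joined <- intToUtf8(all)
        starts <- cumsum(c(1, nchar(seqs)))[seq_along(seqs)]
        substring(joined, starts, starts + nchar(seqs) - 1)
    }
    fwd <- addErrors(fwd); rev <- addErrors(rev)

    # FR on the originating molecule: either end may be mate 1
    swap <- sample(c(TRUE, FALSE), nrow(frags), replace = TRUE)
    r1 <- ifelse(swap, rev, fwd)
    r2 <- ifelse(swap, fwd, rev)
    ids <- sprintf("frag%06d", seq_len(nrow(frags)))
    read1 <- Biostrings::DNAStringSet(r1)
    read2 <- Biostrings::DNAStringSet(r2)
    names(read1) <- paste0(ids, "/1")
    names(read2) <- paste0(ids, "/2")
    frags$sourceName <- c(names(sequences(genome)),
                          names(truthset@derivatives))[frags$src]
    list(read1 = read1, read2 = read2, sources = frags)
}

#' Write simulated reads as a FASTQ pair
#'
#' Flat base quality (Phred 37) per the simulator's noise model.
#'
#' @param reads list from [simulateReads()].
#' @param prefix output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @return invisibly, the two file paths.
#' @export
writeFastqPair <- function(reads, prefix) {
    paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
    for (i in 1:2) {
        rs <- reads[[i]]
        qual <- Biostrings::BStringSet(
            vapply(Biostrings::width(rs),
                   function(w) strrep("F", w), character(1)))
        con <- file(paths[i], "w")
        writeLines(paste0("@", names(rs), "\n", as.character(rs), "\n+\n",
                          as.character(qual)), con, sep = "\n")
        close(con)
    }
    invisible(paths)
}

#' Read a FASTQ pair into memory
#' @param path1,path2 FASTQ paths.
#' @return list with `read1`, `read2` DNAStringSets (names without
#'   trailing `/1`, `/2` kept as written).
#' @export
readFastqPair <- function(path1, path2) {
    list(read1 = Biostrings::readDNAStringSet(path1, format = "fastq"),
         read2 = Biostrings::readDNAStringSet(path2, format = "fastq"))
}
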