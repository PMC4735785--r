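#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a GenomeModel
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp),
#'   or `NULL` to take lengths from `sequences`.
#' @param sequences optional [Biostrings::DNAStringSet-class] (named by
#'   chromosome).
#' @param centromeres [GenomicRanges::GRanges-class] (or `NULL`) of
#'   centromere intervals, 1-based inclusive.
#' @param targetRegions [GenomicRanges::GRanges-class] (or `NULL`) of
#'   capture target intervals, 1-based inclusive.
#' @return a [GenomeModel-class].
#' @examples
#' gm <- GenomeModel(c(chrA = 10000, chrB = 20000))
#' chromLengths(gm)
#' @export
GenomeModel <- function(chromLengths = NULL, sequences = NULL,
                        centromeres = NULL, targetRegions = NULL) {
    if (is.null(sequences)) sequences <- Biostrings::DNAStringSet()
    if (is.null(chromLengths)) {
        if (!length(sequences))
            stop("either chromLengths or sequences must be given")
        chromLengths <- stats::setNames(
            as.numeric(Biostrings::width(sequences)), names(sequences))
    }
    emptyGr <- GenomicRanges::GRanges()
    new("GenomeModel",
        chromLengths = chromLengths,
        sequences = sequences,
        centromeres = if (is.null(centromeres)) emptyGr else centromeres,
        targetRegions = if (is.null(targetRegions)) emptyGr
                        else targetRegions)
}

#' @rdname GenomeModel-class
#' @export
setMethod("chromLengths", "GenomeModel", function(x) x@chromLengths)

#' @rdname GenomeModel-class
#' @export
setMethod("sequences", "GenomeModel", function(x) x@sequences)

#' @rdname GenomeModel-class
#' @export
setMethod("centromeres", "GenomeModel", function(x) x@centromeres)

#' @rdname GenomeModel-class
#' @export
setMethod("targetRegions", "GenomeModel", function(x) x@targetRegions)

setMethod("show", "GenomeModel", function(object) {
    cat(sprintf("GenomeModel with %d chromosome(s), %s kbp total\n",
                length(object@chromLengths),
                format(round(sum(object@chromLengths) / 1000))))
    cat(sprintf("  sequences: %s; centromeres: %d; target regions: %d\n",
                if (length(object@sequences)) "yes" else "no",
                length(object@centromeres), length(object@targetRegions)))
})

#' Extract the (1-based inclusive) sequence of a chromosome interval
#' @keywords internal
refSegment <- function(genome, chrom, start, end) {
    if (!length(sequences(genome)))
        stop("genome carries no sequences")
    as.character(Biostrings::subseq(sequences(genome)[[chrom]],
                                    start = start, end = end))
}

#' Generate a random toy genome
#'
#' Builds a deterministic random reference from chromosome lengths, with
#' optional centromere and target-region annotation, for simulation and
#' testing. Base composition is i.i.d. with a tunable GC fraction.
#'
#' @param chromLengths named numeric vector of lengths (bp, each >= 1000).
#' @param centromeres named list of `c(start, end)` per chromosome, or a
#'   `GRanges`; `NULL` for none.
#' @param targetRegions `GRanges` (or data.frame with chrom/start/end) of
#'   capture targets; `NULL` for none.
#' @param gc GC fraction of the simulated sequence.
#' @param seed integer RNG seed; the same seed reproduces the same
#'   genome byte for byte.
#' @return a [GenomeModel-class] with sequences.
#' @examples
#' gm <- makeToyGenome(c(chrA = 2000, chrB = 3000), seed = 7)
#' @export
makeToyGenome <- function(chromLengths, centromeres = NULL,
                          targetRegions = NULL, gc = 0.5, seed) {
    if (missing(seed)) stop("seed is mandatory")
    if (any(chromLengths < 1000))
        stop("chromosome lengths must be >= 1 kbp")
    if (gc < 0 || gc > 1) stop("gc must be in [0,1]")
    set.seed(as.integer(seed))
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- Biostrings::DNAStringSet(vapply(chromLengths, function(L) {
        paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, character(1)))
    names(seqs) <- names(chromLengths)
    if (is.list(centromeres)) {
        centromeres <- GenomicRanges::GRanges(
            names(centromeres),
            IRanges::IRanges(vapply(centromeres, `[`, numeric(1), 1),
                             vapply(centromeres, `[`, numeric(1), 2)))
    }
    if (is.data.frame(targetRegions)) {
        targetRegions <- GenomicRanges::GRanges(
            targetRegions$chrom,
            IRanges::IRanges(targetRegions$start, targetRegions$end))
    }
    GenomeModel(chromLengths = chromLengths, sequences = seqs,
                centromeres = centromeres, targetRegions = targetRegions)
}
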