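#' @include AllClasses.R AllGenerics.R junctions.R
NULL

#' Segment table of one breakend side
#'
#' Strand semantics, fixed across the package: donor `F` contributes the
#' forward prefix `[1..pos]`; donor `R` the reverse complement of the
#' suffix `[pos..len]`; acceptor `F` the forward suffix `[pos..len]`;
#' acceptor `R` the reverse complement of the prefix `[1..pos]`.
#'
#' @keywords internal
breakendSegment <- function(breakend, role, genome) {
    len <- chromLengths(genome)
    if (!(breakend@chrom %in% names(len)))
        stop(sprintf("chromosome %s not in genome", breakend@chrom))
    L <- len[[breakend@chrom]]
    isPrefix <- (role == "donor") == (breakend@strand == "F")
    ori <- if (breakend@strand == "F") "fwd" else "revcomp"
    if (isPrefix) {
        data.frame(chrom = breakend@chrom, start = 1, end = breakend@pos,
                   orientation = ori, stringsAsFactors = FALSE)
    } else {
        data.frame(chrom = breakend@chrom, start = breakend@pos, end = L,
                   orientation = ori, stringsAsFactors = FALSE)
    }
}

#' Reconstruct the derivative chromosome of a junction
#'
#' Builds the ordered segment list of the fused chromosome and counts
#' the centromeres it carries. Any overlap (>= 1 bp) with an annotated
#' centromere interval counts: the centromere argument is qualitative
#' presence/absence. A derivative without a centromere (the orientation
#' type `a` product) is mitotically nonviable; a type `b` product is
#' dicentric (count 2), flagged but allowed.
#'
#' @param junction a [Junction-class].
#' @param genome a [GenomeModel-class] with centromere annotation.
#' @return a [DerivativeChromosome-class].
#' @examples
#' gm <- GenomeModel(c(chrX = 1000, chrY = 1000),
#'     centromeres = GenomicRanges::GRanges(c("chrX", "chrY"),
#'         IRanges::IRanges(c(600, 100), c(650, 150))))
#' der <- buildDerivative(Junction(Breakend("chrX", 300, "F"),
#'                                 Breakend("chrY", 700, "R")), gm)
#' centromereCount(der)  # 1
#' @export
buildDerivative <- function(junction, genome) {
    if (!length(centromeres(genome)))
        stop("genome has no centromere annotation; counting requires it")
    segs <- rbind(breakendSegment(donor(junction), "donor", genome),
                  breakendSegment(acceptor(junction), "acceptor", genome))
    segGr <- GenomicRanges::GRanges(segs$chrom,
                                    IRanges::IRanges(segs$start, segs$end))
    hits <- GenomicRanges::findOverlaps(centromeres(genome), segGr)
    nCen <- length(unique(S4Vectors::queryHits(hits)))
    new("DerivativeChromosome", segments = segs,
        centromereCount = as.numeric(nCen), viable = nCen >= 1)
}

#' @rdname DerivativeChromosome-class
#' @export
setMethod("segments", "DerivativeChromosome", function(x) x@segments)
#' @rdname DerivativeChromosome-class
#' @export
setMethod("centromereCount", "DerivativeChromosome",
          function(x) x@centromereCount)
#' @rdname DerivativeChromosome-class
#' @export
setMethod("isViable", "DerivativeChromosome", function(x) x@viable)

setMethod("show", "DerivativeChromosome", function(object) {
    segs <- object@segments
    desc <- paste(sprintf("%s:%g-%g(%s)", segs$chrom, segs$start,
                          segs$end, segs$orientation), collapse = " + ")
    status <- if (object@centromereCount == 0) "acentric (nonviable)"
              else if (object@centromereCount >= 2) "dicentric"
              else "monocentric"
    cat(sprintf("DerivativeChromosome %s  [%s]\n", desc, status))
})

#' Sequence of a derivative chromosome
#'
#' @param derivative a [DerivativeChromosome-class] (or its segment
#'   data.frame).
#' @param genome a [GenomeModel-class] with sequences.
#' @param insertedSeq untemplated sequence placed between the two
#'   segments (default "").
#' @return character sequence of the derivative.
#' @export
derivativeSequence <- function(derivative, genome, insertedSeq = "") {
    segs <- if (is(derivative, "DerivativeChromosome"))
        segments(derivative) else derivative
    pieces <- vapply(seq_len(nrow(segs)), function(i) {
        s <- refSegment(genome, segs$chrom[i], segs$start[i], segs$end[i])
        if (segs$orientation[i] == "revcomp") revcomp(s) else s
    }, character(1))
    if (nrow(segs) == 2 && nzchar(insertedSeq))
        paste0(pieces[1], insertedSeq, pieces[2])
    else paste(pieces, collapse = "")
}
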