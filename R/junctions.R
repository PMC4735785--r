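#' @include AllClasses.R AllGenerics.R utils.R genome.R
NULL

#' Construct a Breakend
#'
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @param strand `"F"` or `"R"`.
#' @return a [Breakend-class].
#' @export
Breakend <- function(chrom, pos, strand) {
    new("Breakend", chrom = as.character(chrom), pos = as.numeric(pos),
        strand = as.character(strand))
}

setMethod("show", "Breakend", function(object) {
    cat(sprintf("Breakend %s:%s (%s)\n", object@chrom,
                format(object@pos, big.mark = ",", scientific = FALSE),
                object@strand))
})

#' Construct a Junction
#'
#' @param donor,acceptor [Breakend-class] objects (or `c(chrom, pos,
#'   strand)` vectors): the segments flowing into and out of the joint.
#' @param microhomologyLen shared bases at the joint (default 0).
#' @param insertedSeq untemplated inserted sequence (default "").
#' @param supportPairs,supportSplit evidence read counts.
#' @param flankSeq fused flanking sequence, if available.
#' @return a [Junction-class].
#' @examples
#' j <- Junction(Breakend("chr12", 12023837, "F"),
#'               Breakend("chr21", 36315905, "R"))
#' classifyType(j)
#' @export
Junction <- function(donor, acceptor, microhomologyLen = 0,
                     insertedSeq = "", supportPairs = 0, supportSplit = 0,
                     flankSeq = "") {
    asBe <- function(x) {
        if (is(x, "Breakend")) x else Breakend(x[[1]], x[[2]], x[[3]])
    }
    new("Junction", donor = asBe(donor), acceptor = asBe(acceptor),
        microhomologyLen = as.numeric(microhomologyLen),
        insertedSeq = toupper(as.character(insertedSeq)),
        supportPairs = as.numeric(supportPairs),
        supportSplit = as.numeric(supportSplit),
        flankSeq = as.character(flankSeq))
}

#' @rdname Junction-class
#' @export
setMethod("donor", "Junction", function(x) x@donor)
#' @rdname Junction-class
#' @export
setMethod("acceptor", "Junction", function(x) x@acceptor)
#' @rdname Junction-class
#' @export
setMethod("microhomologyLen", "Junction", function(x) x@microhomologyLen)
#' @rdname Junction-class
#' @export
setMethod("insertedSeq", "Junction", function(x) x@insertedSeq)
#' @rdname Junction-class
#' @export
setMethod("supportPairs", "Junction", function(x) x@supportPairs)
#' @rdname Junction-class
#' @export
setMethod("supportSplit", "Junction", function(x) x@supportSplit)
#' @rdname Junction-class
#' @export
setMethod("flankSeq", "Junction", function(x) x@flankSeq)

setMethod("show", "Junction", function(object) {
    cat(sprintf(
        "Junction %s:%s(%s) -> %s:%s(%s)  hom=%d ins=%dbp  pairs=%d split=%d\n",
        object@donor@chrom,
        format(object@donor@pos, big.mark = ",", scientific = FALSE),
        object@donor@strand,
        object@acceptor@chrom,
        format(object@acceptor@pos, big.mark = ",", scientific = FALSE),
        object@acceptor@strand,
        as.integer(object@microhomologyLen), nchar(object@insertedSeq),
        as.integer(object@supportPairs), as.integer(object@supportSplit)))
})

#' Mirror a junction
#'
#' A junction read from the other side of the joint:
#' `((c1,p1,s1),(c2,p2,s2)) -> ((c2,p2,flip s2),(c1,p1,flip s1))`. The
#' mirror describes the same fused molecule (its reverse complement), so
#' `mirrorJunction` is an involution.
#'
#' @param junction a [Junction-class].
#' @return the mirrored [Junction-class].
#' @export
mirrorJunction <- function(junction) {
    d <- donor(junction); a <- acceptor(junction)
    ins <- insertedSeq(junction)
    Junction(
        donor = Breakend(a@chrom, a@pos, flipStrand(a@strand)),
        acceptor = Breakend(d@chrom, d@pos, flipStrand(d@strand)),
        microhomologyLen = microhomologyLen(junction),
        insertedSeq = if (nzchar(ins)) revcomp(ins) else "",
        supportPairs = supportPairs(junction),
        supportSplit = supportSplit(junction),
        flankSeq = if (nzchar(flankSeq(junction)))
            revcomp(flankSeq(junction)) else "")
}

#' Canonicalize a junction
#'
#' Canonical form places the donor on the earlier chromosome in natural
#' order (chr1 < ... < chr22 < chrX < chrY); same-chromosome junctions
#' put the smaller coordinate on the donor side. A junction and its
#' mirror have the same canonical form, making junction identity
#' well-defined.
#'
#' @param junction a [Junction-class].
#' @return the canonical [Junction-class].
#' @export
canonicalJunction <- function(junction) {
    d <- donor(junction); a <- acceptor(junction)
    rd <- chromRank(d@chrom); ra <- chromRank(a@chrom)
    if (rd > ra || (rd == ra && d@pos > a@pos))
        mirrorJunction(junction)
    else junction
}

#' Stable identity key of a junction (canonical breakends only)
#' @keywords internal
junctionKey <- function(junction) {
    j <- canonicalJunction(junction)
    sprintf("%s:%g:%s|%s:%g:%s", j@donor@chrom, j@donor@pos,
            j@donor@strand, j@acceptor@chrom, j@acceptor@pos,
            j@acceptor@strand)
}

#' Sort a list of junctions canonically
#' @keywords internal
sortJunctions <- function(junctions) {
    junctions <- lapply(junctions, canonicalJunction)
    o <- order(vapply(junctions, function(j) chromRank(j@donor@chrom),
                      numeric(1)),
               vapply(junctions, function(j) j@donor@pos, numeric(1)),
               vapply(junctions, function(j) chromRank(j@acceptor@chrom),
                      numeric(1)),
               vapply(junctions, function(j) j@acceptor@pos, numeric(1)))
    junctions[o]
}

#' Classify a primary-pair junction into orientation types a-d
#'
#' A junction whose breakends both lie on the primary chromosome pair
#' (default chr12/chr21) is typed by its strand pair after placing the
#' donor on the first chromosome of the pair: forward/forward (FF) is
#' type `a`, reverse/reverse (RR) type `b`, forward/reverse (FR) type
#' `c` (the classic ETV6-RUNX1 fusion) and reverse/forward (RF) type
#' `d` (its reciprocal product).
#'
#' @param junction a [Junction-class].
#' @param primaryPair character vector of the two chromosomes, donor
#'   chromosome first.
#' @return one of `"a"`, `"b"`, `"c"`, `"d"`.
#' @examples
#' classifyType(Junction(Breakend("chr12", 12023837, "F"),
#'                       Breakend("chr21", 36315905, "R")))  # "c"
#' @export
classifyType <- function(junction, primaryPair = c("chr12", "chr21")) {
    j <- canonicalJunction(junction)
    d <- donor(j); a <- acceptor(j)
    if (!(d@chrom %in% primaryPair) || !(a@chrom %in% primaryPair) ||
        d@chrom == a@chrom)
        stop("not a primary-pair junction")
    if (d@chrom != primaryPair[1]) j <- mirrorJunction(j)
    key <- paste0(donor(j)@strand, acceptor(j)@strand)
    switch(key, FF = "a", RR = "b", FR = "c", RF = "d")
}

#' Does a junction lie entirely on the primary chromosome pair?
#' @keywords internal
isPrimaryPair <- function(junction, primaryPair = c("chr12", "chr21")) {
    d <- donor(junction); a <- acceptor(junction)
    d@chrom %in% primaryPair && a@chrom %in% primaryPair &&
        d@chrom != a@chrom
}

#' Fused sequence around a junction
#'
#' Concatenates the donor-side flank (the last `flankBp` bases of the
#' donor segment), the untemplated inserted sequence and the
#' acceptor-side flank, honouring the strand semantics of
#' [buildDerivative()]. Flanks are clipped at chromosome ends.
#'
#' @param junction a [Junction-class].
#' @param genome a [GenomeModel-class] with sequences.
#' @param flankBp flank length per side (default 300).
#' @return list with `seq` (character), `offset` (bases before the
#'   junction, i.e. donor flank length) and `clipped` (logical).
#' @export
junctionSequence <- function(junction, genome, flankBp = 300) {
    d <- donor(junction); a <- acceptor(junction)
    len <- chromLengths(genome)
    donorFlank <- if (d@strand == "F") {
        s <- max(1, d@pos - flankBp + 1)
        refSegment(genome, d@chrom, s, d@pos)
    } else {
        e <- min(len[[d@chrom]], d@pos + flankBp - 1)
        revcomp(refSegment(genome, d@chrom, d@pos, e))
    }
    acceptorFlank <- if (a@strand == "F") {
        e <- min(len[[a@chrom]], a@pos + flankBp - 1)
        refSegment(genome, a@chrom, a@pos, e)
    } else {
        s <- max(1, a@pos - flankBp + 1)
        revcomp(refSegment(genome, a@chrom, s, a@pos))
    }
    clipped <- nchar(donorFlank) < flankBp || nchar(acceptorFlank) < flankBp
    list(seq = paste0(donorFlank, insertedSeq(junction), acceptorFlank),
         offset = nchar(donorFlank), clipped = clipped)
}
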