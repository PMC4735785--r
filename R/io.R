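#' @include AllClasses.R junctions.R cohort.R
NULL

#' Write junctions as a breakpoint-table TSV
#'
#' Tab-separated, header row, no thousands separators; donor maps to
#' the `Left_*` columns and acceptor to `Right_*`.
#'
#' @param callset a [SampleCallset-class] (or list of them).
#' @param path output path.
#' @param genes optional `GRanges` with `name` column used to annotate
#'   the gene columns; unannotated breakends get `"."`.
#' @return invisibly, `path`.
#' @export
writeJunctionTable <- function(callset, path, genes = NULL) {
    if (is(callset, "SampleCallset")) callset <- list(callset)
    geneAt <- function(chrom, pos) {
        if (is.null(genes)) return(".")
        hit <- as.character(GenomicRanges::seqnames(genes)) == chrom &
            GenomicRanges::start(genes) <= pos &
            GenomicRanges::end(genes) >= pos
        if (any(hit)) S4Vectors::mcols(genes)$name[which(hit)[1]] else "."
    }
    rows <- list()
    for (cs in callset) {
        for (j in junctions(cs)) {
            d <- donor(j); a <- acceptor(j)
            mode <- tryCatch(classifyType(j), error = function(e) "")
            rows[[length(rows) + 1]] <- data.frame(
                Sample = sampleId(cs), Left_chr = d@chrom,
                Left_str = d@strand, Left_breakpoint = format(d@pos,
                    scientific = FALSE, trim = TRUE),
                Gene_left = geneAt(d@chrom, d@pos),
                Right_chr = a@chrom, Right_str = a@strand,
                Right_breakpoint = format(a@pos, scientific = FALSE,
                                          trim = TRUE),
                Gene_right = geneAt(a@chrom, a@pos), Mode = mode,
                stringsAsFactors = FALSE)
        }
    }
    tbl <- if (length(rows)) do.call(rbind, rows) else
        data.frame(Sample = character(0), Left_chr = character(0),
                   Left_str = character(0), Left_breakpoint = character(0),
                   Gene_left = character(0), Right_chr = character(0),
                   Right_str = character(0),
                   Right_breakpoint = character(0),
                   Gene_right = character(0), Mode = character(0))
    utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read capture target regions from BED
#'
#' BED is 0-based half-open; coordinates are converted to the package's
#' 1-based inclusive convention at this boundary.
#'
#' @param path BED file.
#' @return `GRanges` (1-based inclusive, with `name` column if present).
#' @export
readTargetsBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    GenomicRanges::granges(gr, use.mcols = TRUE)
}

# ---------------------------------------------------------------------
# VCF 4.2 breakend records
# ---------------------------------------------------------------------

# ALT string for a record at `this` breakend joined to `other`:
# this F / other F -> t[c:p[ ; F/R -> t]c:p] ; R/F -> [c:p[t ; R/R -> ]c:p]t
bndAlt <- function(ref, thisStrand, otherChrom, otherPos, otherStrand) {
    loc <- sprintf("%s:%d", otherChrom, as.integer(otherPos))
    if (thisStrand == "F") {
        if (otherStrand == "F") sprintf("%s[%s[", ref, loc)
        else sprintf("%s]%s]", ref, loc)
    } else {
        if (otherStrand == "F") sprintf("[%s[%s", loc, ref)
        else sprintf("]%s]%s", loc, ref)
    }
}

#' Write junctions as VCF 4.2 breakend (BND) records
#'
#' Each junction yields two mated BND records: one at the donor
#' breakend describing the join to the acceptor, and one at the mirror
#' breakend. INFO carries `SVTYPE=BND`, `MATEID`, `HOMLEN`,
#' `SUPPORT_PAIRS` and `SUPPORT_SPLIT`.
#'
#' @param callset a [SampleCallset-class].
#' @param genome a [GenomeModel-class]; REF bases come from its
#'   sequences when available, else `N`.
#' @param path output path.
#' @param seed optional seed recorded as a `##seed=` header line.
#' @return invisibly, `path`.
#' @export
writeVcfBnd <- function(callset, genome, path, seed = NULL) {
    len <- chromLengths(genome)
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##source=svfusion %s",
                     as.character(utils::packageVersion("svfusion"))),
             if (!is.null(seed)) sprintf("##seed=%d", as.integer(seed)),
             sprintf("##contig=<ID=%s,length=%d>", names(len),
                     as.integer(len)),
             "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
             "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend ID\">",
             "##INFO=<ID=HOMLEN,Number=1,Type=Integer,Description=\"Microhomology length\">",
             "##INFO=<ID=SUPPORT_PAIRS,Number=1,Type=Integer,Description=\"Supporting discordant pairs\">",
             "##INFO=<ID=SUPPORT_SPLIT,Number=1,Type=Integer,Description=\"Supporting split reads\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    refBase <- function(chrom, pos) {
        if (!length(sequences(genome))) return("N")
        refSegment(genome, chrom, pos, pos)
    }
    lines <- character(0)
    js <- junctions(callset)
    for (i in seq_along(js)) {
        j <- js[[i]]
        m <- mirrorJunction(j)
        ids <- sprintf("bnd_%d_%d", i, 1:2)
        info <- sprintf(
            "SVTYPE=BND;MATEID=%%s;HOMLEN=%d;SUPPORT_PAIRS=%d;SUPPORT_SPLIT=%d",
            as.integer(microhomologyLen(j)), as.integer(supportPairs(j)),
            as.integer(supportSplit(j)))
        recs <- list(j, m)
        for (r in 1:2) {
            dd <- donor(recs[[r]]); aa <- acceptor(recs[[r]])
            ref <- refBase(dd@chrom, dd@pos)
            lines <- c(lines, paste(
                dd@chrom, as.integer(dd@pos), ids[r], ref,
                bndAlt(ref, dd@strand, aa@chrom, aa@pos, aa@strand),
                ".", "PASS", sprintf(info, ids[3 - r]), sep = "\t"))
        }
    }
    writeLines(c(hdr, lines), path)
    invisible(path)
}

# parse one breakend ALT string; returns list(thisStrand, chrom, pos,
# otherStrand) or NULL for non-BND ALTs
parseBndAlt <- function(alt) {
    m <- regmatches(alt, regexec(
        "^([ACGTN]*)([\\[\\]])([^\\[\\]:]+):([0-9]+)([\\[\\]])([ACGTN]*)$",
        alt, perl = TRUE))[[1]]
    if (!length(m)) return(NULL)
    before <- nzchar(m[2])   # base precedes bracket -> this side F
    bracket <- m[3]
    list(thisStrand = if (before) "F" else "R",
         chrom = m[4], pos = as.numeric(m[5]),
         otherStrand = if (bracket == "[") "F" else "R")
}

#' Read junctions from a VCF of breakend records
#'
#' Mated records are collapsed to one canonical junction each.
#'
#' @param path VCF file.
#' @return list of [Junction-class].
#' @export
readVcfBnd <- function(path) {
    vcf <- VariantAnnotation::readVcf(path)
    gr <- SummarizedExperiment::rowRanges(vcf)
    alts <- vapply(as.list(gr$ALT), function(a)
        as.character(a)[1], character(1))
    info <- VariantAnnotation::info(vcf)
    out <- list()
    for (i in seq_along(gr)) {
        p <- parseBndAlt(alts[i])
        if (is.null(p)) next
        j <- canonicalJunction(Junction(
            Breakend(as.character(GenomicRanges::seqnames(gr)[i]),
                     GenomicRanges::start(gr)[i], p$thisStrand),
            Breakend(p$chrom, p$pos, p$otherStrand),
            microhomologyLen = if (!is.null(info$HOMLEN[i]) &&
                                   !is.na(info$HOMLEN[i]))
                info$HOMLEN[i] else 0,
            supportPairs = if (!is.null(info$SUPPORT_PAIRS[i]) &&
                               !is.na(info$SUPPORT_PAIRS[i]))
                info$SUPPORT_PAIRS[i] else 0,
            supportSplit = if (!is.null(info$SUPPORT_SPLIT[i]) &&
                               !is.na(info$SUPPORT_SPLIT[i]))
                info$SUPPORT_SPLIT[i] else 0))
        out[[junctionKey(j)]] <- j
    }
    unname(out)
}
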