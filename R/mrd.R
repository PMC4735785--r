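#' @include AllClasses.R junctions.R
NULL

#' Export patient-specific fusion sequences for MRD assay design
#'
#' Writes one FASTA record per junction: donor flank + untemplated
#' insertion + acceptor flank. These fused genomic sequences are
#' patient-specific markers usable to track minimal residual disease
#' by quantitative PCR. The default 300 bp flank leaves room for
#' amplicon design on either side of the joint.
#'
#' @param callset a [SampleCallset-class].
#' @param genome a [GenomeModel-class] with sequences.
#' @param flankBp flank length per side (default 300).
#' @param fastaPath,manifestPath optional output paths; when `NULL`
#'   nothing is written and the objects are returned only.
#' @return list with `fasta` ([Biostrings::DNAStringSet-class], ids
#'   `<sample>_<n>_<type>`), `manifest` (data.frame with coordinates,
#'   orientation type, junction offset, clipping warnings).
#' @export
exportMrdTargets <- function(callset, genome, flankBp = 300,
                             fastaPath = NULL, manifestPath = NULL) {
    js <- junctions(callset)     # already canonically sorted
    seqs <- character(0)
    rows <- list()
    for (i in seq_along(js)) {
        j <- js[[i]]
        fl <- junctionSequence(j, genome, flankBp = flankBp)
        if (fl$clipped)
            warning(sprintf("junction %d: flank clipped at chromosome end",
                            i))
        type <- tryCatch(classifyType(j), error = function(e) "x")
        id <- sprintf("%s_%d_%s", sampleId(callset), i, type)
        seqs[id] <- fl$seq
        d <- donor(j); a <- acceptor(j)
        rows[[i]] <- data.frame(
            id = id, sample = sampleId(callset),
            donor_chrom = d@chrom, donor_pos = d@pos,
            donor_strand = d@strand,
            acceptor_chrom = a@chrom, acceptor_pos = a@pos,
            acceptor_strand = a@strand, type = type,
            microhomology = microhomologyLen(j),
            insertion = insertedSeq(j),
            junction_offset = fl$offset,
            seq_length = nchar(fl$seq),
            clipped = fl$clipped, stringsAsFactors = FALSE)
    }
    fasta <- Biostrings::DNAStringSet(seqs)
    manifest <- if (length(rows)) do.call(rbind, rows) else
        data.frame(id = character(0))
    if (!is.null(fastaPath))
        Biostrings::writeXStringSet(fasta, fastaPath)
    if (!is.null(manifestPath))
        utils::write.table(manifest, manifestPath, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    list(fasta = fasta, manifest = manifest)
}
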