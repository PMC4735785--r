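#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#' @importFrom IRanges IRanges
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

#' GenomeModel: chromosomes, centromeres and capture target regions
#'
#' Container for a (toy or real) reference: chromosome names and lengths,
#' optional sequences, centromere intervals and capture target regions.
#' All coordinates are 1-based inclusive.
#'
#' @slot chromLengths named numeric vector of chromosome lengths (bp).
#' @slot sequences [Biostrings::DNAStringSet-class] of chromosome
#'   sequences, or an empty set when only coordinates are modelled.
#' @slot centromeres [GenomicRanges::GRanges-class] of centromere
#'   intervals, at most one per chromosome.
#' @slot targetRegions [GenomicRanges::GRanges-class] of capture target
#'   intervals.
#' @exportClass GenomeModel
setClass("GenomeModel",
    representation(
        chromLengths = "numeric",
        sequences = "DNAStringSet",
        centromeres = "GRanges",
        targetRegions = "GRanges"
    )
)

setValidity("GenomeModel", function(object) {
    msg <- character(0)
    len <- object@chromLengths
    if (is.null(names(len)) || any(!nzchar(names(len))))
        msg <- c(msg, "chromosome lengths must be named")
    if (any(len < 1)) msg <- c(msg, "chromosome lengths must be >= 1")
    if (length(object@sequences)) {
        if (!all(names(object@sequences) %in% names(len)))
            msg <- c(msg, "sequence names must match chromosome names")
        w <- Biostrings::width(object@sequences)
        if (!all(w == len[names(object@sequences)]))
            msg <- c(msg, "sequence widths must equal chromosome lengths")
    }
    checkGr <- function(gr, what) {
        bad <- !(as.character(GenomicRanges::seqnames(gr)) %in% names(len))
        if (any(bad))
            return(sprintf("%s on unknown chromosome", what))
        ends <- GenomicRanges::end(gr)
        lim <- len[as.character(GenomicRanges::seqnames(gr))]
        if (any(GenomicRanges::start(gr) < 1) || any(ends > lim))
            return(sprintf("%s outside chromosome bounds", what))
        NULL
    }
    msg <- c(msg, checkGr(object@centromeres, "centromere"),
             checkGr(object@targetRegions, "target region"))
    if (length(msg)) msg else TRUE
})

#' Breakend: one side of a structural-variant joint
#'
#' A chromosome, a 1-based position and a strand flag. Strand `F` means
#' the forward-strand chain participates in the joint; `R` means the
#' reverse-complement chain does (see [buildDerivative()] for the exact
#' segment semantics).
#'
#' @slot chrom chromosome name.
#' @slot pos 1-based position (bp).
#' @slot strand `"F"` or `"R"`.
#' @exportClass Breakend
setClass("Breakend",
    representation(chrom = "character", pos = "numeric", strand = "character")
)

setValidity("Breakend", function(object) {
    msg <- character(0)
    if (length(object@chrom) != 1 || !nzchar(object@chrom))
        msg <- c(msg, "chrom must be a single non-empty string")
    if (length(object@pos) != 1 || is.na(object@pos) || object@pos < 1)
        msg <- c(msg, "pos must be a single positive coordinate")
    if (length(object@strand) != 1 || !(object@strand %in% c("F", "R")))
        msg <- c(msg, "strand must be 'F' or 'R'")
    if (length(msg)) msg else TRUE
})

#' Junction: a fused pair of breakends
#'
#' The central object of the package: one joint between a donor segment
#' (flowing into the fusion) and an acceptor segment (flowing out of it),
#' with microhomology, untemplated inserted sequence, read support and an
#' optional fused flanking sequence.
#'
#' @slot donor,acceptor [Breakend-class] objects.
#' @slot microhomologyLen identical bases shared by both sides at the
#'   joint (>= 0); the breakpoint is ambiguous within that interval.
#' @slot insertedSeq untemplated bases at the joint (possibly empty).
#' @slot supportPairs discordant read pairs supporting the junction.
#' @slot supportSplit split reads crossing the junction.
#' @slot flankSeq fused sequence around the joint ("" when not attached).
#' @exportClass Junction
setClass("Junction",
    representation(
        donor = "Breakend",
        acceptor = "Breakend",
        microhomologyLen = "numeric",
        insertedSeq = "character",
        supportPairs = "numeric",
        supportSplit = "numeric",
        flankSeq = "character"
    ),
    prototype(microhomologyLen = 0, insertedSeq = "",
              supportPairs = 0, supportSplit = 0, flankSeq = "")
)

setValidity("Junction", function(object) {
    msg <- character(0)
    if (object@microhomologyLen < 0)
        msg <- c(msg, "microhomologyLen must be >= 0")
    if (length(object@insertedSeq) != 1)
        msg <- c(msg, "insertedSeq must be a single string")
    if (length(msg)) msg else TRUE
})

#' SampleCallset: all junctions called for one sample
#'
#' @slot sample sample identifier.
#' @slot junctions list of [Junction-class] objects (canonical order).
#' @slot provenance free-form list (parameters, seed, input paths).
#' @exportClass SampleCallset
setClass("SampleCallset",
    representation(sample = "character", junctions = "list",
                   provenance = "list"),
    prototype(provenance = list())
)

setValidity("SampleCallset", function(object) {
    ok <- vapply(object@junctions, is, logical(1), class2 = "Junction")
    if (!all(ok)) "junctions must all be Junction objects" else TRUE
})

#' InsertSizeModel: robust location/scale of concordant insert sizes
#'
#' @slot center median separation distance of concordant FR pairs (bp).
#' @slot spread robust SD estimate, 1.4826 * MAD (bp).
#' @slot nPairs number of pairs used.
#' @slot unimodal logical flag from a coarse-histogram mode count.
#' @exportClass InsertSizeModel
setClass("InsertSizeModel",
    representation(center = "numeric", spread = "numeric",
                   nPairs = "numeric", unimodal = "logical")
)

setValidity("InsertSizeModel", function(object) {
    if (object@spread < 0) "spread must be >= 0" else TRUE
})

#' DerivativeChromosome: ordered segments fused at a junction
#'
#' @slot segments data.frame with columns `chrom`, `start`, `end`,
#'   `orientation` (`"fwd"` or `"revcomp"`), one row per segment in
#'   derivative order.
#' @slot centromereCount number of centromere intervals overlapped by the
#'   segments (>= 1 bp overlap counts).
#' @slot viable `TRUE` iff at least one centromere is present; dicentric
#'   derivatives (count 2) are flagged viable but reported as dicentric
#'   by [show()].
#' @exportClass DerivativeChromosome
setClass("DerivativeChromosome",
    representation(segments = "data.frame", centromereCount = "numeric",
                   viable = "logical")
)

#' RearrangementEvent: an interpreted set of junctions
#'
#' @slot junctions list of [Junction-class].
#' @slot eventClass one of `two_way_simple`, `two_way_reciprocal`,
#'   `three_way`, `homologous_joint`, `other`.
#' @slot partnerChromosomes chromosomes involved beyond the primary pair.
#' @slot derivatives list of [DerivativeChromosome-class].
#' @exportClass RearrangementEvent
setClass("RearrangementEvent",
    representation(junctions = "list", eventClass = "character",
                   partnerChromosomes = "character", derivatives = "list"),
    prototype(partnerChromosomes = character(0), derivatives = list())
)

setValidity("RearrangementEvent", function(object) {
    cls <- c("two_way_simple", "two_way_reciprocal", "three_way",
             "homologous_joint", "other")
    if (!(object@eventClass %in% cls))
        return(sprintf("eventClass must be one of %s",
                       paste(cls, collapse = ", ")))
    TRUE
})

#' FishProbePanel: dual-colour probe set for FISH pattern prediction
#'
#' @slot probes [GenomicRanges::GRanges-class] with metadata column
#'   `color` in `{green, red}`.
#' @slot minDetectableBp smallest probe fragment producing a visible
#'   signal (bp).
#' @exportClass FishProbePanel
setClass("FishProbePanel",
    representation(probes = "GRanges", minDetectableBp = "numeric")
)

setValidity("FishProbePanel", function(object) {
    msg <- character(0)
    if (!("color" %in% names(S4Vectors::mcols(object@probes))))
        msg <- c(msg, "probes need a 'color' metadata column")
    else if (!all(S4Vectors::mcols(object@probes)$color %in%
                  c("green", "red")))
        msg <- c(msg, "probe color must be 'green' or 'red'")
    if (object@minDetectableBp <= 0)
        msg <- c(msg, "minDetectableBp must be > 0")
    if (length(msg)) msg else TRUE
})

#' TruthSet: simulated junctions plus their derivative sequences
#'
#' Produced by [applyJunctions()]; every truth junction is
#' reconstructable from the derivative sequences by exact string
#' matching.
#'
#' @slot junctions list of [Junction-class] (truth coordinates,
#'   leftmost-aligned under microhomology).
#' @slot derivatives [Biostrings::DNAStringSet-class] of derivative
#'   chromosome sequences, one per junction.
#' @slot derivativeSegments list of segment data.frames (as in
#'   [DerivativeChromosome-class]) mapping derivative coordinates back to
#'   the reference.
#' @slot genome the [GenomeModel-class] the derivatives were built from
#'   (including any bases edited to engineer microhomology).
#' @exportClass TruthSet
setClass("TruthSet",
    representation(junctions = "list", derivatives = "DNAStringSet",
                   derivativeSegments = "list", genome = "GenomeModel")
)

#' SimulationConfig: parameters of the capture-sequencing read simulator
#'
#' Defaults mirror the assay the package models: 350-400 bp
#' size-selected libraries sequenced as 100 bp paired reads, so insert
#' mean 375 bp / SD 35 bp, with capture enrichment around the target
#' regions.
#'
#' @slot seed integer RNG seed (mandatory; no hidden global RNG).
#' @slot readLen read length (bp).
#' @slot insertMean,insertSd truncated-normal fragment-length model (bp).
#' @slot depth fold coverage over the target regions.
#' @slot baseErrorRate per-base substitution probability.
#' @slot captureMargin slack around target regions kept by the capture
#'   emulation (bp).
#' @slot offTargetRate fraction of read pairs drawn genome-wide.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(seed = "numeric", readLen = "numeric",
                   insertMean = "numeric", insertSd = "numeric",
                   depth = "numeric", baseErrorRate = "numeric",
                   captureMargin = "numeric", offTargetRate = "numeric")
)

setValidity("SimulationConfig", function(object) {
    msg <- character(0)
    if (object@insertMean <= 0) msg <- c(msg, "insertMean must be > 0")
    if (object@insertSd < 0) msg <- c(msg, "insertSd must be >= 0")
    if (object@depth <= 0) msg <- c(msg, "depth must be > 0")
    for (r in c("baseErrorRate", "offTargetRate")) {
        v <- slot(object, r)
        if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must be in [0,1]", r))
    }
    if (length(object@seed) != 1 || is.na(object@seed))
        msg <- c(msg, "seed is mandatory")
    if (length(msg)) msg else TRUE
})

#' SvCallingParams: thresholds of the junction-calling procedure
#'
#' Numeric thresholds of the SV procedure: mapping quality strictly
#' greater than `mqMin`, separation deviation strictly greater than
#' `kSd` standard deviations, breakpoint windows of `windowBp`
#' (500-1000 bp), split reads rejected when a read end carries `>=
#' maxUnalignedEndBp` unaligned bases, and support requiring at least
#' `minCrossBases` bases beyond the junction on both sides.
#'
#' @slot mqMin mapping-quality floor (strict: MQ must be > mqMin).
#' @slot kSd insert-size deviation multiplier.
#' @slot windowBp read-extraction half-window around a predicted
#'   breakpoint; constrained to \[500, 1000\].
#' @slot maxUnalignedEndBp exclusive bound on unaligned read-end bases.
#' @slot minCrossBases minimum bases crossing the junction on each side.
#' @slot minClusterPairs minimum discordant pairs per cluster.
#' @slot minSupportReads minimum split-read support per emitted junction.
#' @slot asmMinOverlap,asmMinIdentity greedy-assembly overlap thresholds.
#' @slot flankBp flanking sequence attached to emitted junctions (bp).
#' @exportClass SvCallingParams
setClass("SvCallingParams",
    representation(mqMin = "numeric", kSd = "numeric", windowBp = "numeric",
                   maxUnalignedEndBp = "numeric", minCrossBases = "numeric",
                   minClusterPairs = "numeric", minSupportReads = "numeric",
                   asmMinOverlap = "numeric", asmMinIdentity = "numeric",
                   flankBp = "numeric")
)

setValidity("SvCallingParams", function(object) {
    msg <- character(0)
    if (object@windowBp < 500 || object@windowBp > 1000)
        msg <- c(msg, "windowBp must lie in [500, 1000]")
    pos <- c("mqMin", "kSd", "maxUnalignedEndBp", "minCrossBases",
             "minClusterPairs", "minSupportReads", "asmMinOverlap",
             "flankBp")
    for (p in pos) if (slot(object, p) <= 0)
        msg <- c(msg, sprintf("%s must be positive", p))
    if (object@asmMinIdentity <= 0 || object@asmMinIdentity > 1)
        msg <- c(msg, "asmMinIdentity must be in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' SurvivalResult: two-group Kaplan-Meier and log-rank summary
#'
#' @slot groups group labels (length 2).
#' @slot km named list of per-group Kaplan-Meier step functions as
#'   data.frames with columns `time`, `nRisk`, `nEvent`, `surv`.
#' @slot table per-event-time observed/expected/variance table.
#' @slot chisq log-rank chi-square statistic (1 df).
#' @slot p two-sided p-value.
#' @exportClass SurvivalResult
setClass("SurvivalResult",
    representation(groups = "character", km = "list", table = "data.frame",
                   chisq = "numeric", p = "numeric")
)
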