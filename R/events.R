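#' @include AllClasses.R AllGenerics.R junctions.R derivatives.R
NULL

#' Construct a SampleCallset
#'
#' @param sample sample identifier.
#' @param junctions list of [Junction-class] objects.
#' @param provenance free-form list (parameters, seed, inputs).
#' @return a [SampleCallset-class]; junctions are canonicalized and
#'   sorted.
#' @export
SampleCallset <- function(sample, junctions = list(), provenance = list()) {
    new("SampleCallset", sample = as.character(sample),
        junctions = sortJunctions(junctions), provenance = provenance)
}

#' @rdname SampleCallset-class
#' @export
setMethod("junctions", "SampleCallset", function(x) x@junctions)
#' @rdname SampleCallset-class
#' @export
setMethod("sampleId", "SampleCallset", function(x) x@sample)

setMethod("show", "SampleCallset", function(object) {
    cat(sprintf("SampleCallset '%s' with %d junction(s)\n", object@sample,
                length(object@junctions)))
    for (j in object@junctions) show(j)
})

#' @rdname RearrangementEvent-class
#' @export
setMethod("junctions", "RearrangementEvent", function(x) x@junctions)
#' @rdname RearrangementEvent-class
#' @export
setMethod("eventClass", "RearrangementEvent", function(x) x@eventClass)
#' @rdname RearrangementEvent-class
#' @export
setMethod("partnerChromosomes", "RearrangementEvent",
          function(x) x@partnerChromosomes)
#' @rdname RearrangementEvent-class
#' @export
setMethod("derivatives", "RearrangementEvent", function(x) x@derivatives)

setMethod("show", "RearrangementEvent", function(object) {
    cat(sprintf("RearrangementEvent <%s> with %d junction(s)%s\n",
                object@eventClass, length(object@junctions),
                if (length(object@partnerChromosomes))
                    paste0(", partner: ",
                           paste(object@partnerChromosomes, collapse = ","))
                else ""))
})

#' Interpret a sample's junctions as rearrangement events
#'
#' Groups the junctions called for one sample into biological events:
#'
#' * a primary-pair type-c junction together with two junctions sharing
#'   a third chromosome is a `three_way` translocation (the displaced
#'   ETV6 and RUNX1 remainders fused with the partner chromosome);
#' * a type-b plus type-d pair at distinct breakpoint pairs is a
#'   `homologous_joint` (joint breaks of both homologues of the primary
#'   pair);
#' * a complementary pair on the primary pair (c+d, or a+b) is a
#'   `two_way_reciprocal` balanced translocation;
#' * remaining single junctions are `two_way_simple`; unassignable
#'   groups are `other`.
#'
#' @param junctions list of [Junction-class] (one sample).
#' @param primaryPair the primary chromosome pair (default chr12/chr21).
#' @param genome optional [GenomeModel-class] with centromere
#'   annotation; when given, derivative chromosomes are attached to each
#'   event.
#' @return list of [RearrangementEvent-class].
#' @export
interpretEvents <- function(junctions, primaryPair = c("chr12", "chr21"),
                            genome = NULL) {
    if (!length(junctions)) return(list())
    junctions <- sortJunctions(junctions)
    isPrim <- vapply(junctions, isPrimaryPair, logical(1),
                     primaryPair = primaryPair)
    primary <- junctions[isPrim]
    others <- junctions[!isPrim]

    mkEvent <- function(js, cls, partners = character(0)) {
        ders <- list()
        if (!is.null(genome) && length(centromeres(genome)))
            ders <- lapply(js, buildDerivative, genome = genome)
        new("RearrangementEvent", junctions = js, eventClass = cls,
            partnerChromosomes = partners, derivatives = ders)
    }

    events <- list()
    primTypes <- vapply(primary, classifyType, character(1),
                        primaryPair = primaryPair)

    # partner-chromosome groups (breakends beyond the primary pair)
    offChroms <- lapply(others, function(j) {
        ch <- c(donor(j)@chrom, acceptor(j)@chrom)
        unique(ch[!(ch %in% primaryPair)])
    })
    usedPrimary <- logical(length(primary))
    if (length(others)) {
        for (p in unique(unlist(offChroms))) {
            inGrp <- vapply(offChroms, function(ch) p %in% ch, logical(1))
            grp <- others[inGrp]
            cIdx <- which(primTypes == "c" & !usedPrimary)
            if (length(grp) >= 2 && length(cIdx)) {
                usedPrimary[cIdx[1]] <- TRUE
                events <- c(events, mkEvent(c(primary[cIdx[1]], grp),
                                            "three_way", p))
            } else {
                events <- c(events, mkEvent(grp, "other", p))
            }
        }
    }

    rest <- which(!usedPrimary)
    pairUp <- function(t1, t2, cls) {
        repeat {
            i <- rest[match(t1, primTypes[rest])]
            j <- rest[match(t2, primTypes[rest])]
            if (is.na(i) || is.na(j)) break
            events <<- c(events, mkEvent(primary[c(i, j)], cls))
            rest <<- setdiff(rest, c(i, j))
        }
    }
    pairUp("b", "d", "homologous_joint")
    pairUp("c", "d", "two_way_reciprocal")
    pairUp("a", "b", "two_way_reciprocal")
    for (i in rest)
        events <- c(events, mkEvent(primary[i], "two_way_simple"))
    events
}

#' Construct a FishProbePanel
#'
#' @param probes `GRanges` with metadata column `color` (`green`/`red`),
#'   or a data.frame with columns `color`, `chrom`, `start`, `end`.
#' @param minDetectableBp smallest visible probe fragment (bp).
#' @return a [FishProbePanel-class].
#' @export
FishProbePanel <- function(probes, minDetectableBp = 1000) {
    if (is.data.frame(probes)) {
        gr <- GenomicRanges::GRanges(probes$chrom,
                                     IRanges::IRanges(probes$start,
                                                      probes$end))
        S4Vectors::mcols(gr)$color <- probes$color
        probes <- gr
    }
    new("FishProbePanel", probes = probes,
        minDetectableBp = as.numeric(minDetectableBp))
}

#' Predict dual-colour FISH signal patterns
#'
#' Models the extra-signal dual-colour assay: under a diploid genome,
#' every native homologue not consumed by an event and every derivative
#' chromosome is scanned for probe fragments. A fragment smaller than
#' `minDetectableBp` is invisible; a chromosome carrying detectable
#' fragments of both colours produces a single colocalized (yellow)
#' fusion signal instead of separate green and red ones.
#'
#' Each event consumes one homologue of each chromosome its breakends
#' touch; set `homozygous = TRUE` to let events consume both homologues
#' (the interpretation given to joint homologous breaks).
#'
#' @param events list of [RearrangementEvent-class] (possibly empty).
#' @param genome a [GenomeModel-class].
#' @param panel a [FishProbePanel-class].
#' @param homozygous logical, recycled over events.
#' @return list with `counts` (named numeric: green, red, yellow) and
#'   `detail` (per-chromosome-entity probe content in bp).
#' @export
predictFishPattern <- function(events, genome, panel, homozygous = FALSE) {
    homozygous <- rep_len(homozygous, max(1, length(events)))
    copies <- stats::setNames(rep(2, length(chromLengths(genome))),
                              names(chromLengths(genome)))
    entities <- list()   # each: data.frame(chrom,start,end)
    labels <- character(0)
    for (i in seq_along(events)) {
        ev <- events[[i]]
        involved <- unique(unlist(lapply(junctions(ev), function(j)
            c(donor(j)@chrom, acceptor(j)@chrom))))
        involved <- intersect(involved, names(copies))
        take <- if (homozygous[i]) 2 else 1
        copies[involved] <- pmax(0, copies[involved] - take)
        for (j in junctions(ev)) {
            segs <- rbind(breakendSegment(donor(j), "donor", genome),
                          breakendSegment(acceptor(j), "acceptor", genome))
            rep2 <- if (homozygous[i]) 2 else 1
            for (r in seq_len(rep2)) {
                entities <- c(entities, list(segs))
                labels <- c(labels, sprintf("der_%d_%s>%s", i,
                                            donor(j)@chrom,
                                            acceptor(j)@chrom))
            }
        }
    }
    for (ch in names(copies)) {
        if (copies[ch] > 0) {
            seg <- data.frame(chrom = ch, start = 1,
                              end = chromLengths(genome)[[ch]],
                              orientation = "fwd")
            for (r in seq_len(copies[ch])) {
                entities <- c(entities, list(seg))
                labels <- c(labels, sprintf("native_%s", ch))
            }
        }
    }

    probes <- panel@probes
    counts <- c(green = 0, red = 0, yellow = 0)
    detail <- data.frame(entity = character(0), greenBp = numeric(0),
                         redBp = numeric(0), signal = character(0),
                         undetectedBp = numeric(0))
    for (i in seq_along(entities)) {
        segs <- entities[[i]]
        segGr <- GenomicRanges::GRanges(segs$chrom,
                                        IRanges::IRanges(segs$start,
                                                         segs$end))
        perColor <- c(green = 0, red = 0)
        undet <- 0
        for (k in seq_along(probes)) {
            ov <- GenomicRanges::intersect(
                probes[k], segGr, ignore.strand = TRUE)
            bp <- sum(GenomicRanges::width(ov))
            if (bp == 0) next
            col <- S4Vectors::mcols(probes)$color[k]
            if (bp >= panel@minDetectableBp) perColor[col] <-
                    perColor[col] + bp
            else undet <- undet + bp
        }
        sig <- if (perColor["green"] > 0 && perColor["red"] > 0) "yellow"
               else if (perColor["green"] > 0) "green"
               else if (perColor["red"] > 0) "red"
               else "none"
        if (sig != "none") counts[sig] <- counts[sig] + 1
        detail <- rbind(detail, data.frame(
            entity = labels[i], greenBp = perColor[["green"]],
            redBp = perColor[["red"]], signal = sig, undetectedBp = undet))
    }
    list(counts = counts, detail = detail)
}

#' Compare diagnosis and relapse callsets
#'
#' Junction identity is the canonical breakend pair plus, when both
#' sides carry fused flanking sequence, identity of that sequence. When
#' either callset lacks flank sequences the comparison degrades to
#' coordinates only and the result carries `coordinateOnly = TRUE`.
#'
#' @param diagnosis,relapse [SampleCallset-class] objects.
#' @param flankBp flank bases per side compared (flanks longer than
#'   `2 * flankBp + insertion` are trimmed centrally).
#' @return list with `relation` (`identical`, `shared_subset` or
#'   `disjoint`), `shared`, `lost`, `gained` (junction key vectors) and
#'   `coordinateOnly`.
#' @export
compareClones <- function(diagnosis, relapse, flankBp = 300) {
    jd <- junctions(diagnosis); jr <- junctions(relapse)
    kd <- vapply(jd, junctionKey, character(1))
    kr <- vapply(jr, junctionKey, character(1))
    coordOnly <- FALSE
    trim <- function(s, keep) {
        if (nchar(s) <= keep) return(s)
        off <- floor((nchar(s) - keep) / 2)
        substr(s, off + 1, off + keep)
    }
    sameJunction <- function(a, b) {
        fa <- flankSeq(a); fb <- flankSeq(b)
        if (!nzchar(fa) || !nzchar(fb)) {
            coordOnly <<- TRUE
            return(TRUE)             # coordinates already matched
        }
        keep <- 2 * flankBp + max(nchar(insertedSeq(a)),
                                  nchar(insertedSeq(b)))
        identical(trim(fa, keep), trim(fb, keep))
    }
    common <- intersect(kd, kr)
    shared <- character(0)
    for (k in common) {
        if (sameJunction(jd[[match(k, kd)]], jr[[match(k, kr)]]))
            shared <- c(shared, k)
    }
    lost <- setdiff(kd, shared)
    gained <- setdiff(kr, shared)
    relation <- if (!length(lost) && !length(gained)) "identical"
                else if (!length(shared)) "disjoint"
                else "shared_subset"
    if (!length(kd) && !length(kr)) relation <- "identical"
    list(relation = relation, shared = shared, lost = lost,
         gained = gained, coordinateOnly = coordOnly)
}
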