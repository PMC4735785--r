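#' @include AllClasses.R
NULL

#' @rdname GenomeModel-class
#' @param x a `GenomeModel`.
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname GenomeModel-class
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname GenomeModel-class
#' @export
setGeneric("centromeres", function(x) standardGeneric("centromeres"))

#' @rdname GenomeModel-class
#' @export
setGeneric("targetRegions", function(x) standardGeneric("targetRegions"))

#' @rdname Junction-class
#' @param x a `Junction`.
#' @export
setGeneric("donor", function(x) standardGeneric("donor"))

#' @rdname Junction-class
#' @export
setGeneric("acceptor", function(x) standardGeneric("acceptor"))

#' @rdname Junction-class
#' @export
setGeneric("microhomologyLen", function(x) standardGeneric("microhomologyLen"))

#' @rdname Junction-class
#' @export
setGeneric("insertedSeq", function(x) standardGeneric("insertedSeq"))

#' @rdname Junction-class
#' @export
setGeneric("supportPairs", function(x) standardGeneric("supportPairs"))

#' @rdname Junction-class
#' @export
setGeneric("supportSplit", function(x) standardGeneric("supportSplit"))

#' @rdname Junction-class
#' @export
setGeneric("flankSeq", function(x) standardGeneric("flankSeq"))

#' @rdname SampleCallset-class
#' @param x a `SampleCallset`.
#' @export
setGeneric("junctions", function(x) standardGeneric("junctions"))

#' @rdname SampleCallset-class
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname RearrangementEvent-class
#' @param x a `RearrangementEvent`.
#' @export
setGeneric("eventClass", function(x) standardGeneric("eventClass"))

#' @rdname RearrangementEvent-class
#' @export
setGeneric("partnerChromosomes",
           function(x) standardGeneric("partnerChromosomes"))

#' @rdname RearrangementEvent-class
#' @export
setGeneric("derivatives", function(x) standardGeneric("derivatives"))

#' @rdname DerivativeChromosome-class
#' @param x a `DerivativeChromosome`.
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname DerivativeChromosome-class
#' @export
setGeneric("centromereCount", function(x) standardGeneric("centromereCount"))

#' @rdname DerivativeChromosome-class
#' @export
setGeneric("isViable", function(x) standardGeneric("isViable"))
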