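#' @rdname ActivityTrack
#' @param x an object with an animal identifier.
#' @export
setGeneric("animalId", function(x) standardGeneric("animalId"))

#' @rdname ActivityTrack
#' @export
setGeneric("genotype", function(x) standardGeneric("genotype"))

#' @rdname ActivityTrack
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @rdname ActivityTrack
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname ActivityTrack
#' @export
setGeneric("schedule", function(x) standardGeneric("schedule"))

#' @rdname CellTrace
#' @param x an object with sample times.
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname CellTrace
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname CellTrace
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @rdname BoutTable
#' @param x a `BoutTable`.
#' @export
setGeneric("boutData", function(x) standardGeneric("boutData"))

#' @rdname CosinorFit
#' @param x a `CosinorFit`.
#' @export
setGeneric("mesor", function(x) standardGeneric("mesor"))

#' @rdname CosinorFit
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))

#' @rdname CosinorFit
#' @export
setGeneric("acrophase", function(x) standardGeneric("acrophase"))

#' @rdname CircularSummary
#' @param x a `CircularSummary`.
#' @export
setGeneric("resultantLength", function(x) standardGeneric("resultantLength"))

#' @rdname CircularSummary
#' @export
setGeneric("meanPhase", function(x) standardGeneric("meanPhase"))

#' @rdname CircularSummary
#' @export
setGeneric("rayleighP", function(x) standardGeneric("rayleighP"))
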