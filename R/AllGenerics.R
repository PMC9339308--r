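#' Accessors for ribostall classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object a ribostall S4 object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("transcriptId", function(object) standardGeneric("transcriptId"))

#' @rdname accessors
#' @export
setGeneric("nCodons", function(object) standardGeneric("nCodons"))

#' @rdname accessors
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))

#' @rdname accessors
#' @export
setGeneric("current", function(object) standardGeneric("current"))

#' @rdname accessors
#' @export
setGeneric("footprintCounts", function(object) standardGeneric("footprintCounts"))

#' @rdname accessors
#' @export
setGeneric("totalReads", function(object) standardGeneric("totalReads"))

#' @rdname accessors
#' @export
setGeneric("smoothedDensity", function(object) standardGeneric("smoothedDensity"))

#' @rdname accessors
#' @export
setGeneric("normalizedDensity", function(object) standardGeneric("normalizedDensity"))

#' @rdname accessors
#' @export
setGeneric("regimeLabel", function(object) standardGeneric("regimeLabel"))

#' @rdname accessors
#' @export
setGeneric("elongationRates", function(object) standardGeneric("elongationRates"))

#' @rdname accessors
#' @export
setGeneric("cohortTruth", function(object) standardGeneric("cohortTruth"))

#' @rdname accessors
#' @export
setGeneric("cohortPairs", function(object) standardGeneric("cohortPairs"))
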