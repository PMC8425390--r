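#' @include AllClasses.R
NULL

#' Accessors for map model objects
#'
#' `mapName`, `pools`, `complexes`, `processes`, `compartments` and
#' `provenance` extract the corresponding parts of a [MapModel-class];
#' `poolId` extracts the identifier of a pool or process container object.
#'
#' @param x a model object.
#' @return the slot value.
#' @name map-accessors
#' @aliases mapName pools complexes processes compartments provenance poolId
NULL

#' @rdname map-accessors
#' @export
setGeneric("mapName", function(x) standardGeneric("mapName"))
#' @rdname map-accessors
#' @export
setGeneric("pools", function(x) standardGeneric("pools"))
#' @rdname map-accessors
#' @export
setGeneric("complexes", function(x) standardGeneric("complexes"))
#' @rdname map-accessors
#' @export
setGeneric("processes", function(x) standardGeneric("processes"))
#' @rdname map-accessors
#' @export
setGeneric("compartments", function(x) standardGeneric("compartments"))
#' @rdname map-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname map-accessors
#' @export
setGeneric("poolId", function(x) standardGeneric("poolId"))

#' State signature of a protein pool
#'
#' The ordered, duplicate-free list of state-variable site tokens present on
#' a pool, regardless of their values. Two pools of the same protein with
#' the same signature satisfy the "once a variable, always a variable"
#' convention with respect to each other.
#'
#' @param pool a [ProteinPool-class].
#' @return sorted character vector of site tokens.
#' @examples
#' stateSignature(ProteinPool("p", "RAF1",
#'   state = stateVariables(c("S338", "activity"))))
#' @export
setGeneric("stateSignature", function(pool) standardGeneric("stateSignature"))
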