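#' @include AllGenerics.R
NULL

#' @rdname map-accessors
setMethod("mapName", "MapModel", function(x) x@mapName)
#' @rdname map-accessors
setMethod("pools", "MapModel", function(x) x@pools)
#' @rdname map-accessors
setMethod("complexes", "MapModel", function(x) x@complexes)
#' @rdname map-accessors
setMethod("processes", "MapModel", function(x) x@processes)
#' @rdname map-accessors
setMethod("compartments", "MapModel", function(x) x@compartments)
#' @rdname map-accessors
setMethod("provenance", "MapModel", function(x) x@provenance)
#' @rdname map-accessors
setMethod("poolId", "ProteinPool", function(x) x@poolId)
#' @rdname map-accessors
setMethod("poolId", "ComplexPool", function(x) x@poolId)

#' @describeIn ProteinPool-class compact display
#' @param object a ProteinPool
setMethod("show", "ProteinPool", function(object) {
  st <- object@state
  stStr <- if (length(st)) {
    paste(sprintf("%s:%s", names(st), ifelse(is.na(st), "-", st)),
          collapse = ",")
  } else "-"
  cat(sprintf("ProteinPool '%s' %s [%s]%s state={%s}\n",
              object@poolId, object@label, object@proteinKey,
              if (object@isGeneric)
                sprintf(" generic(%s)", paste(object@members, collapse = ","))
              else "",
              stStr))
})

#' @describeIn MapModel-class compact display
#' @param object a MapModel
setMethod("show", "MapModel", function(object) {
  cat(sprintf("MapModel '%s': %d protein pools, %d complexes, %d processes\n",
              object@mapName, length(object@pools), length(object@complexes),
              length(object@processes)))
  if (!is.na(object@provenance))
    cat(sprintf("  provenance: %s\n", object@provenance))
})

#' Assert the referential integrity of a map model
#'
#' Runs the full validity check (unique pool ids, resolvable
#' cross-references, compartment declarations, per-pool state constraints)
#' and either returns the model invisibly or raises an error.
#'
#' @param model a [MapModel-class].
#' @return the model, invisibly.
#' @export
validateMap <- function(model) {
  stopifnot(is(model, "MapModel"))
  validObject(model)
  for (p in model@pools) validObject(p)
  for (cx in model@complexes) validObject(cx)
  for (pr in model@processes) validObject(pr)
  invisible(model)
}

#' Look up a protein pool by id
#' @param model a [MapModel-class].
#' @param id pool id.
#' @return a [ProteinPool-class] or [ComplexPool-class].
#' @export
getPool <- function(model, id) {
  p <- model@pools[[id]]
  if (is.null(p)) p <- model@complexes[[id]]
  if (is.null(p)) stop(sprintf("no pool '%s' in map '%s'", id, model@mapName))
  p
}

#' @rdname getPool
#' @export
isComplexId <- function(model, id) !is.null(model@complexes[[id]])
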