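#' @include lints.R
NULL

#' Combinatorial expansion of a complex with generic components
#'
#' Enumerates all distinct concrete complexes obtained by substituting each
#' generic component by each of its annotated members, collapsing
#' order-equivalent results (complex composition is a multiset). For a
#' single generic component appearing `m` times with `k` members, the count
#' is the multiset-combination closed form `choose(k + m - 1, m)`: a MEK
#' homo/heterodimer over MEK1 and MEK2 expands to the three members MEK1
#' homodimer, MEK2 homodimer and the MEK1-MEK2 heterodimer. State variables
#' on a generic component are copied to each member instance.
#'
#' @param model the [MapModel-class] owning the complex.
#' @param cx a [ComplexPool-class] or its pool id; must contain at least
#'   one generic component, each with annotated members (a generic without
#'   members cannot be expanded and raises an error).
#' @return a list of concrete complexes, each a list with elements `keys`
#'   (sorted member-key multiset) and `components` (list of
#'   [ProteinPool-class] objects, generic components replaced by specific
#'   member instances carrying the copied state).
#' @examples
#' m <- buildFixture("generic_mek_dimer")
#' length(expandGenericComplex(m, "cx_mek_dimer"))  # 3
#' @export
expandGenericComplex <- function(model, cx) {
  if (is.character(cx)) cx <- getPool(model, cx)
  stopifnot(is(cx, "ComplexPool"))
  comps <- lapply(cx@componentIds, getPool, model = model)
  isGen <- vapply(comps, function(p) isTRUE(p@isGeneric), logical(1))
  if (!any(isGen))
    stop(sprintf("complex '%s' has no generic component to expand",
                 cx@poolId), call. = FALSE)
  options <- lapply(comps, function(p) {
    if (!p@isGeneric) return(p@proteinKey)
    if (!length(p@members))
      stop(sprintf("generic component '%s' of complex '%s' has no annotated members; cannot expand",
                   p@poolId, cx@poolId), call. = FALSE)
    p@members
  })
  grid <- expand.grid(options, stringsAsFactors = FALSE)
  multisets <- apply(grid, 1L, function(row) paste(sort(row), collapse = "+"))
  keep <- !duplicated(multisets)
  out <- lapply(which(keep), function(i) {
    keys <- sort(as.character(unlist(grid[i, ])))
    pools <- lapply(seq_along(comps), function(j) {
      p <- comps[[j]]
      key <- as.character(grid[i, j])
      if (!p@isGeneric) return(p)
      ProteinPool(paste0(p@poolId, "_", key), label = key,
                  proteinKey = key, state = p@state,
                  compartment = p@compartment)
    })
    list(keys = keys, components = pools)
  })
  ord <- order(vapply(out, function(x) paste(x$keys, collapse = "+"),
                      character(1)))
  out[ord]
}
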