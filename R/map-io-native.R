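#' @include identity.R
NULL

.NATIVE_FORMAT_VERSION <- "1.0"

.poolToList <- function(p) {
  st <- p@state
  list(
    pool_id = p@poolId,
    label = p@label,
    protein_key = p@proteinKey,
    uniprot_ids = as.list(p@uniprotIds),
    is_generic = p@isGeneric,
    members = as.list(p@members),
    compartment = p@compartment,
    state = lapply(seq_along(st), function(i) {
      list(site = names(st)[[i]],
           value = if (is.na(st[[i]])) NULL else st[[i]])
    })
  )
}

.processToList <- function(pr) {
  m <- pr@modulators
  ord <- order(m$pool, m$class)
  list(
    process_id = pr@processId,
    kind = pr@kind,
    reactants = as.list(sort(pr@reactants)),
    products = as.list(sort(pr@products)),
    modulators = lapply(ord, function(i) {
      list(pool = m$pool[[i]], class = m$class[[i]])
    })
  )
}

.modelToList <- function(model) {
  list(
    format_version = .NATIVE_FORMAT_VERSION,
    map = list(
      map_name = model@mapName,
      compartments = as.list(sort(model@compartments)),
      pools = unname(lapply(model@pools[order(names(model@pools))],
                            .poolToList)),
      complexes = unname(lapply(model@complexes[order(names(model@complexes))],
                         function(cx) list(pool_id = cx@poolId,
                                           components = as.list(cx@componentIds),
                                           compartment = cx@compartment))),
      processes = unname(lapply(model@processes[order(names(model@processes))],
                                .processToList))
    )
  )
}

#' Write a map in the native JSON interchange format
#'
#' The native format is a canonical, lossless serialization of a
#' [MapModel-class]: fixed key order, pools/complexes/processes sorted by
#' id, state variables sorted by site. Writing the result of
#' [readNativeMap()] reproduces the input byte for byte. Provenance is
#' runtime metadata and is not serialized.
#'
#' @param model a validated [MapModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeNativeMap <- function(model, path) {
  validateMap(model)
  json <- jsonlite::toJSON(.modelToList(model), auto_unbox = TRUE,
                           pretty = 2, digits = NA, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Serialize a map to its canonical native JSON string
#'
#' Useful for structural equality tests: two maps are equal up to pool-id
#' ordering iff their canonical strings are identical.
#'
#' @inheritParams writeNativeMap
#' @return a single JSON string.
#' @export
nativeMapString <- function(model) {
  as.character(jsonlite::toJSON(.modelToList(model), auto_unbox = TRUE,
                                pretty = 2, digits = NA, null = "null"))
}

.nativeFail <- function(path, what) {
  stop(sprintf("native map document invalid at %s: %s", path, what),
       call. = FALSE)
}

.need <- function(x, field, jpath, type = NULL) {
  if (is.null(x[[field]]))
    .nativeFail(paste0(jpath, ".", field), "missing required field")
  v <- x[[field]]
  if (!is.null(type) && !is(v, type))
    .nativeFail(paste0(jpath, ".", field), sprintf("expected %s", type))
  v
}

.chr1 <- function(x, field, jpath) {
  v <- .need(x, field, jpath)
  if (!is.character(v) || length(v) != 1L)
    .nativeFail(paste0(jpath, ".", field), "expected a single string")
  v
}

#' Read a map from the native JSON interchange format
#'
#' Performs structural validation of the document (required fields, types,
#' state-variable shape) with error messages citing the offending JSON
#' path, then builds and validates a [MapModel-class].
#'
#' @param path input file path.
#' @param mapName optional override of the serialized map name.
#' @return a validated [MapModel-class] with `provenance` set to `path`.
#' @export
readNativeMap <- function(path, mapName = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$format_version))
    .nativeFail("$.format_version", "missing required field")
  mp <- .need(doc, "map", "$")
  nm <- mapName %||% .chr1(mp, "map_name", "$.map")
  poolsL <- mp$pools %||% list()
  pools <- lapply(seq_along(poolsL), function(i) {
    jp <- sprintf("$.map.pools[%d]", i - 1L)
    p <- poolsL[[i]]
    stL <- p$state %||% list()
    sites <- vapply(seq_along(stL), function(j) {
      .chr1(stL[[j]], "site", sprintf("%s.state[%d]", jp, j - 1L))
    }, character(1))
    values <- vapply(stL, function(sv) {
      if (is.null(sv$value)) NA_character_ else as.character(sv$value)
    }, character(1))
    ProteinPool(
      poolId = .chr1(p, "pool_id", jp),
      label = .chr1(p, "label", jp),
      proteinKey = .chr1(p, "protein_key", jp),
      uniprotIds = as.character(unlist(p$uniprot_ids %||% list())),
      isGeneric = isTRUE(.need(p, "is_generic", jp)),
      members = as.character(unlist(p$members %||% list())),
      compartment = .chr1(p, "compartment", jp),
      state = stateVariables(sites, values))
  })
  cxL <- mp$complexes %||% list()
  cxs <- lapply(seq_along(cxL), function(i) {
    jp <- sprintf("$.map.complexes[%d]", i - 1L)
    cx <- cxL[[i]]
    comps <- as.character(unlist(.need(cx, "components", jp)))
    if (!length(comps)) .nativeFail(paste0(jp, ".components"), "empty")
    ComplexPool(.chr1(cx, "pool_id", jp), comps,
                compartment = .chr1(cx, "compartment", jp))
  })
  prL <- mp$processes %||% list()
  prs <- lapply(seq_along(prL), function(i) {
    jp <- sprintf("$.map.processes[%d]", i - 1L)
    pr <- prL[[i]]
    kind <- .chr1(pr, "kind", jp)
    if (!kind %in% .PROCESS_KINDS)
      .nativeFail(paste0(jp, ".kind"), sprintf("unknown kind '%s'", kind))
    modsL <- pr$modulators %||% list()
    mods <- data.frame(
      pool = vapply(seq_along(modsL), function(j)
        .chr1(modsL[[j]], "pool", sprintf("%s.modulators[%d]", jp, j - 1L)),
        character(1)),
      class = vapply(seq_along(modsL), function(j)
        .chr1(modsL[[j]], "class", sprintf("%s.modulators[%d]", jp, j - 1L)),
        character(1)),
      stringsAsFactors = FALSE)
    Process(.chr1(pr, "process_id", jp),
            reactants = as.character(unlist(pr$reactants %||% list())),
            products = as.character(unlist(pr$products %||% list())),
            modulators = mods, kind = kind)
  })
  model <- MapModel(nm, pools = pools, complexes = cxs, processes = prs,
                    compartments = as.character(unlist(mp$compartments %||%
                                                         list("default"))),
                    provenance = path)
  validateMap(model)
}
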