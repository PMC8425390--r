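#' @import methods
NULL

## Regex for residue-style site tokens: amino-acid letter + 1-based position
## in UniProt canonical numbering ("S218"). Anything else that is a plain
## word token ("activity") is a named flag.
.RESIDUE_RE <- "^[A-Z][1-9][0-9]*$"

#' Test whether a site token is a residue token
#'
#' Residue tokens are an upper-case amino-acid letter followed by a 1-based
#' position in UniProt canonical numbering (e.g. `"S218"`). Other non-empty
#' word tokens (e.g. `"activity"`) are named flags.
#'
#' @param site character vector of site tokens.
#' @return logical vector.
#' @examples
#' isResidueSite(c("S218", "activity", "Y187"))
#' @export
isResidueSite <- function(site) {
  grepl(.RESIDUE_RE, site)
}

.validSiteToken <- function(site) {
  nzchar(site) & grepl("^[A-Za-z][A-Za-z0-9_]*$", site)
}

## A state-variable set is stored as a named character vector:
## names are site tokens, values are "P" (phosphorylated), another string,
## or NA (unset).
.checkState <- function(state) {
  msgs <- character()
  if (length(state)) {
    sites <- names(state)
    if (is.null(sites) || any(!.validSiteToken(sites)))
      msgs <- c(msgs, "state-variable sites must be non-empty word tokens")
    if (anyDuplicated(sites))
      msgs <- c(msgs, "state-variable sites must be unique within a pool")
    if (!is.character(state))
      msgs <- c(msgs, "state-variable values must be character (NA = unset)")
  }
  msgs
}

#' Build a state-variable set
#'
#' @param sites character vector of site tokens (residues like `"S218"` or
#'   named flags like `"activity"`).
#' @param values character vector of the same length; `"P"` marks a
#'   phosphorylated residue, `NA` an unset variable. Defaults to all unset.
#' @return a named character vector usable as the `state` slot of a
#'   [ProteinPool].
#' @examples
#' stateVariables(c("S218", "S222"), c("P", NA))
#' @export
stateVariables <- function(sites = character(), values = NA_character_) {
  sites <- as.character(sites)
  values <- rep_len(as.character(values), length(sites))
  names(values) <- sites
  bad <- .checkState(values)
  if (length(bad)) stop(paste(bad, collapse = "; "))
  values[order(names(values))]
}

#' ProteinPool: a stateful protein entity pool
#'
#' An entity pool for a protein (specific, identified by one UniProt
#' accession via its `proteinKey`) or a generic protein group (e.g. "MEK"
#' standing for MEK1 and MEK2), carrying a set of state variables.
#'
#' @slot poolId unique pool identifier within a map.
#' @slot label display name.
#' @slot proteinKey identity key (see [normalizeProteinIdentity]).
#' @slot uniprotIds UniProt accessions (possibly empty).
#' @slot isGeneric whether the pool stands for a group of proteins.
#' @slot members protein keys of the group members (non-empty only for
#'   generic pools; a generic with empty members is legal but linted).
#' @slot state named character vector: site token -> value (`"P"`,
#'   another string, or `NA` = unset).
#' @slot compartment compartment id.
#' @aliases ProteinPool-class
#' @exportClass ProteinPool
setClass("ProteinPool",
  representation(
    poolId = "character", label = "character", proteinKey = "character",
    uniprotIds = "character", isGeneric = "logical", members = "character",
    state = "character", compartment = "character"
  ),
  prototype(
    uniprotIds = character(), isGeneric = FALSE, members = character(),
    state = stateVariables(), compartment = "default"
  )
)

setValidity("ProteinPool", function(object) {
  msgs <- character()
  for (sl in c("poolId", "label", "proteinKey", "compartment")) {
    v <- slot(object, sl)
    if (length(v) != 1L || is.na(v) || !nzchar(v))
      msgs <- c(msgs, sprintf("'%s' must be a single non-empty string", sl))
  }
  if (length(object@isGeneric) != 1L || is.na(object@isGeneric))
    msgs <- c(msgs, "'isGeneric' must be TRUE or FALSE")
  else if (!object@isGeneric && length(object@members))
    msgs <- c(msgs, "a specific pool must not carry members")
  msgs <- c(msgs, .checkState(object@state))
  if (length(msgs)) msgs else TRUE
})

#' Construct a ProteinPool
#'
#' @param poolId unique id within the map.
#' @param label display name; also the default identity input.
#' @param state state-variable set, see [stateVariables].
#' @param uniprotIds UniProt accessions.
#' @param isGeneric generic group pool?
#' @param members member protein keys for generic pools.
#' @param compartment compartment id.
#' @param proteinKey identity key; computed with [normalizeProteinIdentity]
#'   from `label` and `uniprotIds` when omitted.
#' @param aliasTable alias table passed to [normalizeProteinIdentity].
#' @return a [ProteinPool-class] object.
#' @examples
#' ProteinPool("p1", "MEK1", state = stateVariables(c("S218", "S222")))
#' @export
ProteinPool <- function(poolId, label, state = stateVariables(),
                        uniprotIds = character(), isGeneric = FALSE,
                        members = character(), compartment = "default",
                        proteinKey = NULL, aliasTable = defaultAliasTable()) {
  if (is.null(proteinKey)) {
    proteinKey <- if (isGeneric) toupper(trimws(label)) else
      normalizeProteinIdentity(label, uniprotIds, aliasTable)
  }
  new("ProteinPool",
    poolId = poolId, label = label, proteinKey = proteinKey,
    uniprotIds = sort(unique(uniprotIds)), isGeneric = isGeneric,
    members = sort(unique(members)),
    state = if (length(state)) state[order(names(state))] else stateVariables(),
    compartment = compartment)
}

#' ComplexPool: a complex entity pool
#'
#' A pool of identical complexes, described by the multiset of protein pools
#' (referenced by pool id) that compose it.
#'
#' @slot poolId unique pool identifier within a map.
#' @slot componentIds pool ids of the component protein pools (a multiset:
#'   ids may repeat, e.g. a homodimer).
#' @slot compartment compartment id.
#' @aliases ComplexPool-class
#' @exportClass ComplexPool
setClass("ComplexPool",
  representation(poolId = "character", componentIds = "character",
                 compartment = "character"),
  prototype(compartment = "default"))

setValidity("ComplexPool", function(object) {
  msgs <- character()
  if (length(object@poolId) != 1L || !nzchar(object@poolId))
    msgs <- c(msgs, "'poolId' must be a single non-empty string")
  if (length(object@componentIds) < 1L)
    msgs <- c(msgs, "a complex must have at least one component")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ComplexPool
#' @param poolId unique id within the map.
#' @param componentIds pool ids of component protein pools (ids may repeat).
#' @param compartment compartment id.
#' @return a [ComplexPool-class] object.
#' @export
ComplexPool <- function(poolId, componentIds, compartment = "default") {
  new("ComplexPool", poolId = poolId, componentIds = sort(componentIds),
      compartment = compartment)
}

.PROCESS_KINDS <- c("state_transition", "association", "dissociation",
                    "generic_process")
.MODULATION_CLASSES <- c("catalysis", "stimulation", "unknown")

#' Process: a PD process node
#'
#' @slot processId unique process identifier within a map.
#' @slot reactants pool ids consumed (multiset).
#' @slot products pool ids produced (multiset).
#' @slot modulators data.frame with columns `pool` (pool id) and `class`
#'   (one of catalysis, stimulation, unknown).
#' @slot kind one of state_transition, association, dissociation,
#'   generic_process.
#' @aliases Process-class
#' @exportClass Process
setClass("Process",
  representation(processId = "character", reactants = "character",
                 products = "character", modulators = "data.frame",
                 kind = "character"),
  prototype(modulators = data.frame(pool = character(), class = character(),
                                    stringsAsFactors = FALSE),
            kind = "state_transition"))

setValidity("Process", function(object) {
  msgs <- character()
  if (length(object@processId) != 1L || !nzchar(object@processId))
    msgs <- c(msgs, "'processId' must be a single non-empty string")
  if (!all(object@kind %in% .PROCESS_KINDS) || length(object@kind) != 1L)
    msgs <- c(msgs, sprintf("'kind' must be one of %s",
                            paste(.PROCESS_KINDS, collapse = ", ")))
  if (identical(object@kind, "state_transition") &&
      (length(object@reactants) == 0L || length(object@products) == 0L))
    msgs <- c(msgs, "state transitions need non-empty reactants and products")
  m <- object@modulators
  if (!all(c("pool", "class") %in% names(m)))
    msgs <- c(msgs, "'modulators' needs columns 'pool' and 'class'")
  else if (nrow(m) && !all(m$class %in% .MODULATION_CLASSES))
    msgs <- c(msgs, sprintf("modulation class must be one of %s",
                            paste(.MODULATION_CLASSES, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a Process
#' @param processId unique id within the map.
#' @param reactants,products pool ids (multisets; ids may repeat).
#' @param modulators either a data.frame with columns `pool`/`class` or a
#'   named character vector `c(poolId = "catalysis", ...)`.
#' @param kind process kind.
#' @return a [Process-class] object.
#' @export
Process <- function(processId, reactants = character(), products = character(),
                    modulators = NULL, kind = "state_transition") {
  if (is.null(modulators)) {
    modulators <- data.frame(pool = character(), class = character(),
                             stringsAsFactors = FALSE)
  } else if (is.character(modulators)) {
    modulators <- data.frame(pool = names(modulators),
                             class = unname(modulators),
                             stringsAsFactors = FALSE)
  }
  new("Process", processId = processId, reactants = sort(reactants),
      products = sort(products), modulators = modulators, kind = kind)
}

#' MapModel: one process description map
#'
#' The in-memory graph model of a PD map: stateful entity pools (proteins
#' and complexes), processes with modulation arcs, compartments, and the map
#' name (the fourth field of phosphorylation quadruplets).
#'
#' @slot mapName map name.
#' @slot pools named list of [ProteinPool-class] objects (names = pool ids).
#' @slot complexes named list of [ComplexPool-class] objects.
#' @slot processes named list of [Process-class] objects.
#' @slot compartments compartment ids.
#' @slot provenance source tag (fixture preset id, file path, "merge", ...).
#' @aliases MapModel-class
#' @exportClass MapModel
setClass("MapModel",
  representation(mapName = "character", pools = "list", complexes = "list",
                 processes = "list", compartments = "character",
                 provenance = "character"),
  prototype(pools = list(), complexes = list(), processes = list(),
            compartments = "default", provenance = NA_character_))

setValidity("MapModel", function(object) {
  msgs <- character()
  if (length(object@mapName) != 1L || is.na(object@mapName) ||
      !nzchar(object@mapName))
    msgs <- c(msgs, "'mapName' must be a single non-empty string")
  poolIds <- vapply(object@pools, function(p) p@poolId, character(1))
  cxIds <- vapply(object@complexes, function(p) p@poolId, character(1))
  allIds <- c(poolIds, cxIds)
  if (anyDuplicated(allIds))
    msgs <- c(msgs, sprintf("duplicated pool ids: %s",
      paste(unique(allIds[duplicated(allIds)]), collapse = ", ")))
  if (length(object@pools) &&
      (is.null(names(object@pools)) || !identical(unname(poolIds),
                                                  names(object@pools))))
    msgs <- c(msgs, "'pools' must be named by pool id")
  if (length(object@complexes) &&
      (is.null(names(object@complexes)) || !identical(unname(cxIds),
                                                      names(object@complexes))))
    msgs <- c(msgs, "'complexes' must be named by pool id")
  for (cx in object@complexes) {
    bad <- setdiff(cx@componentIds, poolIds)
    if (length(bad))
      msgs <- c(msgs, sprintf("complex '%s' references unknown pools: %s",
                              cx@poolId, paste(bad, collapse = ", ")))
  }
  for (pr in object@processes) {
    refs <- c(pr@reactants, pr@products, pr@modulators$pool)
    bad <- setdiff(refs, allIds)
    if (length(bad))
      msgs <- c(msgs, sprintf("process '%s' references unknown pools: %s",
                              pr@processId, paste(bad, collapse = ", ")))
  }
  prIds <- vapply(object@processes, function(p) p@processId, character(1))
  if (anyDuplicated(prIds))
    msgs <- c(msgs, "duplicated process ids")
  cpts <- unique(c(
    vapply(object@pools, function(p) p@compartment, character(1)),
    vapply(object@complexes, function(p) p@compartment, character(1))))
  bad <- setdiff(cpts, object@compartments)
  if (length(bad))
    msgs <- c(msgs, sprintf("pools reference undeclared compartments: %s",
                            paste(bad, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct and validate a MapModel
#'
#' @param mapName the map name (used as the fourth field of phosphorylation
#'   quadruplets).
#' @param pools list of [ProteinPool-class] objects.
#' @param complexes list of [ComplexPool-class] objects.
#' @param processes list of [Process-class] objects.
#' @param compartments compartment ids; compartments used by pools are added
#'   automatically.
#' @param provenance free-text source tag.
#' @return a validated [MapModel-class].
#' @examples
#' m <- MapModel("toy", pools = list(ProteinPool("p1", "RAF1")))
#' mapName(m)
#' @export
MapModel <- function(mapName, pools = list(), complexes = list(),
                     processes = list(), compartments = "default",
                     provenance = NA_character_) {
  poolL <- stats::setNames(pools,
                           vapply(pools, function(x) x@poolId, character(1)))
  cxL <- stats::setNames(complexes,
                         vapply(complexes, function(x) x@poolId, character(1)))
  prL <- stats::setNames(processes,
                         vapply(processes, function(x) x@processId,
                                character(1)))
  cpts <- unique(c(compartments,
    vapply(poolL, function(p) p@compartment, character(1)),
    vapply(cxL, function(p) p@compartment, character(1))))
  obj <- new("MapModel", mapName = mapName, pools = poolL, complexes = cxL,
             processes = prL, compartments = cpts, provenance = provenance)
  validObject(obj)
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a
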