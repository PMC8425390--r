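#' @include census.R
NULL

.finding <- function(ruleId, severity, proteinKey, poolIds, maps, message,
                     payload = list()) {
  out <- data.frame(ruleId = ruleId, severity = severity,
                    proteinKey = proteinKey,
                    pools = paste(poolIds, collapse = ";"),
                    maps = paste(maps, collapse = ";"),
                    message = message, stringsAsFactors = FALSE)
  out$payload <- list(payload)
  out
}

.emptyFindings <- function() {
  out <- data.frame(ruleId = character(), severity = character(),
                    proteinKey = character(), pools = character(),
                    maps = character(), message = character(),
                    stringsAsFactors = FALSE)
  out$payload <- list()
  out
}

.bindFindings <- function(rows) {
  if (!length(rows)) return(.emptyFindings())
  out <- do.call(rbind, rows)
  out <- out[order(out$ruleId, out$proteinKey, out$maps), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.asModelList <- function(models) {
  if (is(models, "MapModel")) models <- list(models)
  stats::setNames(models, vapply(models, mapName, character(1)))
}

#' Lint: "once a variable, always a variable"
#'
#' Checks the state-variable universes of each protein. Within a map, two
#' pools of the same protein carrying different site sets are an error
#' finding (such a map cannot even be drawn consistently in
#' CellDesigner-style notation, and blocks merging). Across maps, a protein
#' whose per-map signature universes differ yields a warning finding whose
#' payload lists the distinct signatures and their count.
#'
#' @param models a [MapModel-class] or list of them.
#' @return a findings data.frame (ruleId STATE_SIGNATURE).
#' @examples
#' lintStateSignature(list(buildFixture("acsn_canonical"),
#'                         buildFixture("acsn_raf1_stateless")))
#' @export
lintStateSignature <- function(models) {
  models <- .asModelList(models)
  rows <- list()
  perMapUniverse <- list()  # proteinKey -> map -> signature string
  for (m in models) {
    byKey <- split(m@pools, vapply(m@pools, function(p) p@proteinKey,
                                   character(1)))
    for (key in names(byKey)) {
      sigs <- lapply(byKey[[key]], stateSignature)
      sigStr <- vapply(sigs, paste, character(1), collapse = ",")
      if (length(unique(sigStr)) > 1L) {
        rows[[length(rows) + 1L]] <- .finding(
          "STATE_SIGNATURE", "error", key,
          vapply(byKey[[key]], poolId, character(1)), m@mapName,
          sprintf("protein %s carries %d different state-variable sets within map '%s'",
                  key, length(unique(sigStr)), m@mapName),
          payload = list(signatures = sort(unique(sigStr))))
      }
      universe <- sort(unique(unlist(sigs)))
      perMapUniverse[[key]] <- c(perMapUniverse[[key]], stats::setNames(
        list(list(universe = universe,
                  poolIds = vapply(byKey[[key]], poolId, character(1)))),
        m@mapName))
    }
  }
  for (key in names(perMapUniverse)) {
    uni <- perMapUniverse[[key]]
    if (length(uni) < 2L) next
    sigStr <- vapply(uni, function(u) paste(u$universe, collapse = ","),
                     character(1))
    names(sigStr) <- names(uni)
    distinct <- sort(unique(sigStr))
    if (length(distinct) > 1L) {
      rows[[length(rows) + 1L]] <- .finding(
        "STATE_SIGNATURE", "warning", key,
        unlist(lapply(uni, `[[`, "poolIds"), use.names = FALSE),
        names(uni),
        sprintf("protein %s has %d distinct state-variable signatures across %d maps",
                key, length(distinct), length(uni)),
        payload = list(nSignatures = length(distinct),
                       signatures = distinct,
                       perMap = sigStr))
    }
  }
  .bindFindings(rows)
}

#' Lint: conflicting generic and specific representations
#'
#' Flags every protein that appears both as a member of a generic group
#' pool in some map and as a specific pool in another (or the same) map
#' (ruleId GENERIC_SPECIFIC, warning). Generic pools whose member list is
#' empty get a separate UNANNOTATED_GENERIC info finding: the specific
#' proteins lumped into a generic entity should be annotated.
#'
#' @inheritParams lintStateSignature
#' @return a findings data.frame.
#' @export
lintGenericSpecific <- function(models) {
  models <- .asModelList(models)
  rows <- list()
  genericOf <- list(); specificOf <- list(); poolsOf <- list()
  for (m in models) {
    for (p in m@pools) {
      if (p@isGeneric) {
        for (mem in p@members)
          poolsOf[[mem]] <- union(poolsOf[[mem]], p@poolId)
        if (!length(p@members)) {
          rows[[length(rows) + 1L]] <- .finding(
            "UNANNOTATED_GENERIC", "info", p@proteinKey, p@poolId,
            m@mapName,
            sprintf("generic pool '%s' (%s) in map '%s' has no annotated members",
                    p@poolId, p@label, m@mapName))
        }
        for (mem in p@members)
          genericOf[[mem]] <- union(genericOf[[mem]], m@mapName)
      } else {
        specificOf[[p@proteinKey]] <- union(specificOf[[p@proteinKey]],
                                            m@mapName)
        poolsOf[[p@proteinKey]] <- union(poolsOf[[p@proteinKey]], p@poolId)
      }
    }
  }
  for (key in sort(intersect(names(genericOf), names(specificOf)))) {
    maps <- sort(union(genericOf[[key]], specificOf[[key]]))
    rows[[length(rows) + 1L]] <- .finding(
      "GENERIC_SPECIFIC", "warning", key, poolsOf[[key]], maps,
      sprintf("protein %s is lumped into a generic pool in map(s) %s but specific in map(s) %s",
              key, paste(sort(genericOf[[key]]), collapse = ", "),
              paste(sort(specificOf[[key]]), collapse = ", ")),
      payload = list(genericMaps = sort(genericOf[[key]]),
                     specificMaps = sort(specificOf[[key]])))
  }
  .bindFindings(rows)
}

#' Reference table of canonical activating phosphosites
#'
#' User-configurable data, not hard-coded biology: maps protein identity
#' keys to the phosphosite set conventionally marking the active kinase.
#' Defaults cover MEK1 (S218/S222), ERK1 (T202/Y204) and ERK2 (T185/Y187);
#' the MEK2 pair S222/S226 is the conventional homologous pair and is
#' shipped for completeness.
#'
#' @param sites optional named list overriding/extending the defaults,
#'   protein key -> character vector of residue tokens.
#' @return named list of residue-token sets.
#' @export
canonicalSiteReference <- function(sites = NULL) {
  ref <- list(
    Q02750 = c("S218", "S222"),   # MEK1
    P36507 = c("S222", "S226"),   # MEK2
    P27361 = c("T202", "Y204"),   # ERK1
    P28482 = c("T185", "Y187"))   # ERK2
  if (!is.null(sites)) ref[names(sites)] <- sites
  ok <- vapply(ref, function(s) all(isResidueSite(s)), logical(1))
  if (!all(ok))
    stop("canonical site reference must contain residue tokens only")
  ref
}

#' Lint: non-canonical phosphosite sets
#'
#' For every specific protein pool covered by the reference table, compares
#' the set of residues phosphorylated on the pool (value `"P"`) with the
#' canonical activating set. Pools whose phosphosite set is empty or equals
#' the reference are silent; others are flagged (warning) and classified as
#' superset, disjoint or other. Proteins absent from the reference are
#' skipped with an info-level note (one per protein).
#'
#' @inheritParams lintStateSignature
#' @param reference a [canonicalSiteReference()].
#' @return a findings data.frame (ruleId CANONICAL_SITES).
#' @export
lintCanonicalSites <- function(models, reference = canonicalSiteReference()) {
  models <- .asModelList(models)
  rows <- list(); noted <- character()
  for (m in models) {
    for (p in m@pools) {
      if (p@isGeneric) next
      st <- p@state
      obs <- names(st)[!is.na(st) & st == "P" & isResidueSite(names(st))]
      if (!length(obs)) next
      ref <- reference[[p@proteinKey]]
      if (is.null(ref)) {
        if (!p@proteinKey %in% noted) {
          noted <- c(noted, p@proteinKey)
          rows[[length(rows) + 1L]] <- .finding(
            "CANONICAL_SITES", "info", p@proteinKey, p@poolId, m@mapName,
            sprintf("protein %s not covered by the canonical-site reference; skipped",
                    p@proteinKey))
        }
        next
      }
      obs <- sort(obs)
      if (setequal(obs, ref)) next
      cls <- if (all(ref %in% obs)) "superset"
             else if (!length(intersect(obs, ref))) "disjoint" else "other"
      rows[[length(rows) + 1L]] <- .finding(
        "CANONICAL_SITES", "warning", p@proteinKey, p@poolId, m@mapName,
        sprintf("pool '%s': %s phosphorylated at {%s}, canonical active set is {%s} (%s)",
                p@poolId, p@proteinKey, paste(obs, collapse = ","),
                paste(sort(ref), collapse = ","), cls),
        payload = list(observed = obs, reference = sort(ref),
                       class = cls))
    }
  }
  .bindFindings(rows)
}

#' Lint: complex versus free-cascade variants
#'
#' For each complex in each map, looks in the other maps for (a) a complex
#' over the same proteins but with a different composition signature
#' (states or multiplicities differ), or (b) a process among free pools
#' whose protein participants match the complex's components one-to-one —
#' i.e. the signalling the complex encapsulates drawn as split events with
#' free entities. Matching is by bijective pairing of per-component
#' identity-key sets (so a generic RAF component matches a specific RAF1
#' pool); without generics this is exact protein-set equality. Subset or
#' superset matching is available via `allowSubset` (higher recall, more
#' noise).
#'
#' @inheritParams lintStateSignature
#' @param allowSubset also report when a map's free process covers a strict
#'   subset of the complex's components (default `FALSE`).
#' @return a findings data.frame (ruleId COMPLEX_VARIANT, warning).
#' @export
lintComplexVariants <- function(models, allowSubset = FALSE) {
  models <- .asModelList(models)
  if (length(models) < 2L) return(.emptyFindings())
  rows <- list()
  cxDesc <- list()
  for (m in models) {
    for (cx in m@complexes) {
      cxDesc[[length(cxDesc) + 1L]] <- list(
        map = m@mapName, id = cx@poolId,
        label = .complexLabel(m, cx),
        keySets = lapply(cx@componentIds, .identityKeys, model = m),
        signature = paste(complexCompositionSignature(m, cx,
                                                      withValues = TRUE),
                          collapse = "+"))
    }
  }
  ## (a) same protein set, different composition
  if (length(cxDesc) > 1L) {
    seen <- character()
    for (i in seq_along(cxDesc)) for (j in seq_along(cxDesc)) {
      if (i >= j) next
      a <- cxDesc[[i]]; b <- cxDesc[[j]]
      if (a$map == b$map) next
      if (!.keySetsMatch(a$keySets, b$keySets)) next
      if (identical(a$signature, b$signature)) next
      tag <- paste(sort(c(paste(a$map, a$id), paste(b$map, b$id))),
                   collapse = "|")
      if (tag %in% seen) next
      seen <- c(seen, tag)
      rows[[length(rows) + 1L]] <- .finding(
        "COMPLEX_VARIANT", "warning", a$label, c(a$id, b$id),
        c(a$map, b$map),
        sprintf("complex over the same proteins composed differently: '%s' in '%s' vs '%s' in '%s'",
                a$id, a$map, b$id, b$map),
        payload = list(signatures = c(a$signature, b$signature)))
    }
  }
  ## (b) complex in one map vs free-pool process in another
  for (d in cxDesc) {
    for (m in models) {
      if (m@mapName == d$map) next
      for (pr in m@processes) {
        partIds <- unique(c(pr@reactants, pr@products, pr@modulators$pool))
        freeIds <- partIds[!vapply(partIds, isComplexId, logical(1),
                                   model = m)]
        if (length(freeIds) != length(partIds)) next  # complexes involved
        keys <- unique(vapply(freeIds,
                              function(id) getPool(m, id)@proteinKey,
                              character(1)))
        keySets <- lapply(freeIds[!duplicated(vapply(freeIds,
          function(id) getPool(m, id)@proteinKey, character(1)))],
          .identityKeys, model = m)
        hit <- .keySetsMatch(d$keySets, keySets) ||
          (allowSubset && length(keySets) < length(d$keySets) &&
             .keySetsSubset(keySets, d$keySets))
        if (hit) {
          rows[[length(rows) + 1L]] <- .finding(
            "COMPLEX_VARIANT", "warning", d$label,
            c(d$id, pr@processId), c(d$map, m@mapName),
            sprintf("proteins of complex '%s' (map '%s') interact as free pools in process '%s' of map '%s'",
                    d$id, d$map, pr@processId, m@mapName),
            payload = list(complex = d$signature,
                           process = pr@processId,
                           freeKeys = sort(keys)))
        }
      }
    }
  }
  .bindFindings(rows)
}

## Bijective matching of two lists of identity-key sets: every component of
## a pairs with a distinct component of b such that key sets intersect.
.keySetsMatch <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  .matchRec(a, b)
}

.matchRec <- function(a, b) {
  if (!length(a)) return(TRUE)
  for (j in seq_along(b)) {
    if (length(intersect(a[[1]], b[[j]])) &&
        .matchRec(a[-1], b[-j])) return(TRUE)
  }
  FALSE
}

.keySetsSubset <- function(a, b) {
  ## every set in a matches some distinct set in b
  if (!length(a)) return(TRUE)
  for (j in seq_along(b)) {
    if (length(intersect(a[[1]], b[[j]])) &&
        .keySetsSubset(a[-1], b[-j])) return(TRUE)
  }
  FALSE
}

#' Run all composability lints
#'
#' @inheritParams lintStateSignature
#' @param rules subset of rule ids to run.
#' @param reference canonical-site reference for CANONICAL_SITES.
#' @return combined findings data.frame.
#' @export
lintMaps <- function(models,
                     rules = c("STATE_SIGNATURE", "GENERIC_SPECIFIC",
                               "CANONICAL_SITES", "COMPLEX_VARIANT"),
                     reference = canonicalSiteReference()) {
  models <- .asModelList(models)
  out <- list()
  if (any(c("STATE_SIGNATURE") %in% rules))
    out <- c(out, list(lintStateSignature(models)))
  if (any(c("GENERIC_SPECIFIC", "UNANNOTATED_GENERIC") %in% rules))
    out <- c(out, list(lintGenericSpecific(models)))
  if ("CANONICAL_SITES" %in% rules)
    out <- c(out, list(lintCanonicalSites(models, reference)))
  if ("COMPLEX_VARIANT" %in% rules && length(models) >= 2L)
    out <- c(out, list(lintComplexVariants(models)))
  out <- out[vapply(out, nrow, integer(1)) > 0L]
  .bindFindings(out)
}
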