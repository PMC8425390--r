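#' @include identity.R
NULL

.emptyEvents <- function() {
  data.frame(kinase = character(), target = character(), site = character(),
             map = character(), mode = character(), processId = character(),
             targetGeneric = logical(), expanded = logical(),
             stringsAsFactors = FALSE)
}

## Sites gained by product pool p relative to reactant pool r: sites whose
## value is "P" on p and absent or unset on r. Dephosphorylation (a site
## lost) is deliberately not an event.
.gainedSites <- function(rPool, pPool) {
  ps <- pPool@state
  phos <- names(ps)[!is.na(ps) & ps == "P"]
  rs <- rPool@state
  phos[vapply(phos, function(s)
    !(s %in% names(rs)) || is.na(rs[[s]]), logical(1))]
}

## Pair changed complex components between a reactant and a product complex.
## The two complexes must be identical except for the target's gained
## site(s): after cancelling components with identical (key, full state),
## the remainders must pair one-to-one by protein key.
.complexDiffPairs <- function(model, rcx, pcx) {
  rPools <- lapply(rcx@componentIds, getPool, model = model)
  pPools <- lapply(pcx@componentIds, getPool, model = model)
  rSig <- vapply(rPools, .poolFullKey, character(1))
  pSig <- vapply(pPools, .poolFullKey, character(1))
  ## cancel common components (multiset intersection)
  for (s in rSig) {
    j <- match(s, pSig)
    if (!is.na(j)) {
      pSig[j] <- NA_character_
      rSig[match(s, rSig)] <- NA_character_
    }
  }
  rRem <- which(!is.na(rSig)); pRem <- which(!is.na(pSig))
  if (length(rRem) == 0L || length(rRem) != length(pRem)) return(NULL)
  rKeys <- vapply(rPools[rRem], function(p) p@proteinKey, character(1))
  pKeys <- vapply(pPools[pRem], function(p) p@proteinKey, character(1))
  if (!identical(sort(rKeys), sort(pKeys))) return(NULL)
  pairs <- list()
  used <- logical(length(pRem))
  for (i in seq_along(rRem)) {
    j <- which(!used & pKeys == rKeys[[i]])[1L]
    if (is.na(j)) return(NULL)
    used[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- list(r = rPools[[rRem[[i]]]],
                                        p = pPools[[pRem[[j]]]])
  }
  pairs
}

.eventRow <- function(model, kinId, tgtPool, site, mode, processId,
                      expanded = FALSE, kinaseName = NULL,
                      targetName = NULL) {
  data.frame(
    kinase = kinaseName %||% .recordedName(model, kinId),
    target = targetName %||% tgtPool@proteinKey,
    site = site, map = model@mapName, mode = mode, processId = processId,
    targetGeneric = tgtPool@isGeneric, expanded = expanded,
    stringsAsFactors = FALSE)
}

#' Extract catalyzed phosphorylation events from a map
#'
#' Walks every process of the map and emits one event per gained
#' phosphorylation site, in two matching modes mirroring the free-protein
#' and in-complex queries of the underlying workflow:
#'
#' * free mode: a reactant protein pool and a product protein pool share a
#'   protein identity, the product carries a site with value `"P"` that is
#'   absent or unset on the reactant, and the process has a modulator of
#'   class catalysis (optionally also stimulation).
#' * in-complex mode: a reactant complex and a product complex are
#'   identical except for the target component's gained site(s).
#'
#' Each event is the quadruplet (kinase, target, site, map) plus mode and
#' process provenance. Specific pools are recorded under their protein key,
#' generic pools under their generic label key, complex catalysts under a
#' composition label. A residue gained as a non-residue flag (e.g. an
#' `activity` variable turning `"P"`) yields site token `""` (site
#' unspecified). Exact duplicate quadruplets from one process are
#' deduplicated; distinct processes each count.
#'
#' @param model a validated [MapModel-class].
#' @param modulationClasses modulator classes accepted as "catalyzed";
#'   default catalysis only.
#' @param expandGenerics additionally emit one row per member of a generic
#'   kinase/target (cartesian when both are generic), flagged
#'   `expanded = TRUE`; the label-level rows are kept.
#' @return data.frame with columns kinase, target, site, map, mode,
#'   processId, targetGeneric, expanded.
#' @examples
#' extractPhosphoEvents(buildFixture("acsn_emt_raf1_detailed"))
#' @export
extractPhosphoEvents <- function(model,
                                 modulationClasses = "catalysis",
                                 expandGenerics = FALSE) {
  validateMap(model)
  rows <- list()
  for (pr in model@processes) {
    mods <- pr@modulators
    kinIds <- mods$pool[mods$class %in% modulationClasses]
    if (!length(kinIds)) next
    for (kinId in unique(kinIds)) {
      ## free proteins
      rp <- pr@reactants[!vapply(pr@reactants, isComplexId, logical(1),
                                 model = model)]
      pp <- pr@products[!vapply(pr@products, isComplexId, logical(1),
                                model = model)]
      for (r in rp) for (p in pp) {
        rPool <- getPool(model, r); pPool <- getPool(model, p)
        if (!identical(rPool@proteinKey, pPool@proteinKey)) next
        for (s in .gainedSites(rPool, pPool)) {
          rows[[length(rows) + 1L]] <- .eventRow(
            model, kinId, pPool, if (isResidueSite(s)) s else "",
            "free", pr@processId)
        }
      }
      ## proteins inside complexes
      rc <- pr@reactants[vapply(pr@reactants, isComplexId, logical(1),
                                model = model)]
      pc <- pr@products[vapply(pr@products, isComplexId, logical(1),
                               model = model)]
      for (r in rc) for (p in pc) {
        pairs <- .complexDiffPairs(model, getPool(model, r),
                                   getPool(model, p))
        if (is.null(pairs)) next
        ok <- TRUE
        gained <- lapply(pairs, function(pair)
          .gainedSites(pair$r, pair$p))
        if (any(vapply(gained, length, integer(1)) == 0L)) ok <- FALSE
        if (!ok) next
        for (i in seq_along(pairs)) {
          for (s in gained[[i]]) {
            rows[[length(rows) + 1L]] <- .eventRow(
              model, kinId, pairs[[i]]$p,
              if (isResidueSite(s)) s else "", "in_complex", pr@processId)
          }
        }
      }
    }
  }
  ev <- if (length(rows)) do.call(rbind, rows) else .emptyEvents()
  ev <- unique(ev)  # dedup identical quadruplets from one process
  if (expandGenerics && nrow(ev)) {
    ex <- list()
    for (i in seq_len(nrow(ev))) {
      kKeys <- .eventIdentityKeys(model, ev$kinase[[i]])
      tKeys <- .eventIdentityKeys(model, ev$target[[i]])
      if (length(kKeys) > 1L || length(tKeys) > 1L ||
          !identical(kKeys, ev$kinase[[i]]) ||
          !identical(tKeys, ev$target[[i]])) {
        for (k in kKeys) for (t in tKeys) {
          r <- ev[i, , drop = FALSE]
          r$kinase <- k; r$target <- t; r$expanded <- TRUE
          ex[[length(ex) + 1L]] <- r
        }
      }
    }
    if (length(ex)) ev <- unique(rbind(ev, do.call(rbind, ex)))
  }
  ev <- ev[do.call(order, ev), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

## Identity keys for a recorded event name: resolve generic labels and
## complex labels through the map's pools.
.eventIdentityKeys <- function(model, recordedName) {
  for (p in model@pools) {
    if (identical(p@proteinKey, recordedName)) {
      return(if (p@isGeneric && length(p@members)) p@members
             else recordedName)
    }
  }
  for (cx in model@complexes) {
    if (identical(.complexLabel(model, cx), recordedName))
      return(.identityKeys(model, cx@poolId))
  }
  recordedName
}

#' Group phosphorylation events into a cross-map pattern census
#'
#' Groups events by the map-free triplet (kinase, target, site) and counts,
#' per map, the number of distinct processes yielding the triplet. Rows are
#' ordered triplet-lexicographically.
#'
#' @param events event data.frame from [extractPhosphoEvents()] (rows from
#'   several maps may be concatenated with `rbind`); expanded rows are
#'   excluded from counting.
#' @return a `PatternCensus` data.frame with columns kinase, target, site,
#'   nMaps, total, maps (readable `map=count` summary) and a list-column
#'   perMap of named per-map counts.
#' @export
groupPatterns <- function(events) {
  ev <- events[!events$expanded, , drop = FALSE]
  if (!nrow(ev)) {
    out <- data.frame(kinase = character(), target = character(),
                      site = character(), nMaps = integer(),
                      total = integer(), maps = character(),
                      stringsAsFactors = FALSE)
    out$perMap <- list()
    class(out) <- c("PatternCensus", class(out))
    return(out)
  }
  key <- paste(ev$kinase, ev$target, ev$site, sep = "\r")
  rows <- lapply(split(ev, key), function(g) {
    perMap <- vapply(split(g$processId, g$map),
                     function(x) length(unique(x)), integer(1))
    perMap <- perMap[order(names(perMap))]
    data.frame(kinase = g$kinase[[1]], target = g$target[[1]],
               site = g$site[[1]], nMaps = length(perMap),
               total = sum(perMap),
               maps = paste(sprintf("%s=%d", names(perMap), perMap),
                            collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$perMap <- lapply(split(ev, key), function(g)
    vapply(split(g$processId, g$map), function(x) length(unique(x)),
           integer(1)))
  ord <- order(out$kinase, out$target, out$site)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("PatternCensus", class(out))
  out
}

#' Keep only repeated patterns
#'
#' Discards census rows whose total occurrence (summed over maps) is below
#' `minTotal`; the default keeps patterns seen at least twice, i.e. drops
#' the non-repeated ones.
#'
#' @param census a census from [groupPatterns()].
#' @param minTotal minimum total occurrence to keep (default 2).
#' @return the filtered census (a subset of the input rows).
#' @export
filterRepeated <- function(census, minTotal = 2L) {
  out <- census[census$total >= minTotal, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find repeated patterns represented differently across maps
#'
#' Groups phosphorylation events into kinase/target groups using
#' identity-key overlap (a generic pool matches through its annotated
#' members, a complex catalyst through its components), then inspects each
#' group that is repeated (two or more events). A group is divergent when
#' its per-map representations differ in any of: the target's state
#' signature, the target's generic-versus-specific status, the set of
#' gained sites, or the free-versus-in-complex matching mode.
#'
#' @param models named list of [MapModel-class] objects (names ignored; map
#'   names come from the models).
#' @param census optional [groupPatterns()] census restricting which
#'   triplets participate; by default all extracted events do.
#' @param modulationClasses passed to [extractPhosphoEvents()].
#' @return data.frame with one row per group: kinases, targets, maps,
#'   nMaps, nVersions, divergent, reasons, and a list-column `evidence` of
#'   per-map representation descriptors.
#' @export
findDivergentRepresentations <- function(models, census = NULL,
                                         modulationClasses = "catalysis") {
  evs <- list(); reps <- list()
  for (m in models) {
    ev <- extractPhosphoEvents(m, modulationClasses = modulationClasses)
    if (!nrow(ev)) next
    ev$kinKeys <- lapply(ev$kinase, .eventIdentityKeys, model = m)
    ev$tgtKeys <- lapply(ev$target, .eventIdentityKeys, model = m)
    ev$tgtSig <- vapply(seq_len(nrow(ev)), function(i) {
      sig <- .targetSignatureInMap(m, ev$target[[i]])
      paste(sig, collapse = ",")
    }, character(1))
    evs[[length(evs) + 1L]] <- ev
  }
  if (!length(evs)) return(.emptyDivergence())
  ev <- do.call(rbind, evs)
  if (!is.null(census)) {
    keep <- paste(ev$kinase, ev$target, ev$site) %in%
      paste(census$kinase, census$target, census$site)
    ev <- ev[keep, , drop = FALSE]
    if (!nrow(ev)) return(.emptyDivergence())
  }
  ## connected components: events linked when kinase identity sets and
  ## target identity sets both intersect
  n <- nrow(ev)
  edges <- integer()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (length(intersect(ev$kinKeys[[i]], ev$kinKeys[[j]])) &&
          length(intersect(ev$tgtKeys[[i]], ev$tgtKeys[[j]])))
        edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership

  rows <- lapply(split(seq_len(n), comp), function(idx) {
    grp <- ev[idx, , drop = FALSE]
    maps <- sort(unique(grp$map))
    perMap <- lapply(maps, function(mn) {
      gm <- grp[grp$map == mn, , drop = FALSE]
      list(map = mn,
           mode = sort(unique(gm$mode)),
           targetGeneric = sort(unique(gm$targetGeneric)),
           targetSignature = sort(unique(gm$tgtSig)),
           sites = sort(unique(gm$site)))
    })
    tuple <- vapply(perMap, function(d) paste(
      paste(d$mode, collapse = "/"),
      paste(d$targetGeneric, collapse = "/"),
      paste(d$targetSignature, collapse = "/"),
      paste(d$sites, collapse = "/"), sep = " | "), character(1))
    nVersions <- length(unique(tuple))
    reasons <- character()
    if (length(unique(unlist(lapply(perMap, `[[`, "targetSignature")))) > 1L)
      reasons <- c(reasons, "state_signature")
    if (length(unique(unlist(lapply(perMap, `[[`, "targetGeneric")))) > 1L)
      reasons <- c(reasons, "generic_vs_specific")
    if (length(unique(vapply(perMap, function(d)
      paste(d$sites, collapse = ","), character(1)))) > 1L)
      reasons <- c(reasons, "site_detail")
    if (length(unique(unlist(lapply(perMap, `[[`, "mode")))) > 1L)
      reasons <- c(reasons, "mode")
    out <- data.frame(
      kinases = paste(sort(unique(grp$kinase)), collapse = ";"),
      targets = paste(sort(unique(grp$target)), collapse = ";"),
      maps = paste(maps, collapse = ";"),
      nMaps = length(maps),
      nEvents = nrow(grp),
      nVersions = nVersions,
      repeated = nrow(grp) >= 2L,
      divergent = nrow(grp) >= 2L && length(reasons) > 0L,
      reasons = paste(reasons, collapse = ","),
      stringsAsFactors = FALSE)
    out$evidence <- list(perMap)
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$kinases, out$targets), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.emptyDivergence <- function() {
  out <- data.frame(kinases = character(), targets = character(),
                    maps = character(), nMaps = integer(),
                    nEvents = integer(), nVersions = integer(),
                    repeated = logical(), divergent = logical(),
                    reasons = character(), stringsAsFactors = FALSE)
  out$evidence <- list()
  out
}

## State signature of the pools recorded under a name in a map (union over
## pools with that recorded name).
.targetSignatureInMap <- function(model, recordedName) {
  sigs <- character()
  for (p in model@pools) {
    if (identical(p@proteinKey, recordedName))
      sigs <- union(sigs, stateSignature(p))
  }
  sort(sigs)
}
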