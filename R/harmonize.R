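#' @include expand.R
NULL

#' Propagate a state-variable universe over all pools of a protein
#'
#' Implements the harmonization step behind the "once a variable, always a
#' variable" rule: after propagation, every pool of the protein carries
#' exactly the given site set. Values already present are preserved; newly
#' added variables are unset. Processes are untouched. The operation is
#' idempotent and monotone (site sets only grow); a universe missing a site
#' already present on some pool is an error, since applying it would lose
#' information.
#'
#' @param model a [MapModel-class].
#' @param proteinKey the protein identity key to harmonize.
#' @param universe character vector of site tokens; must be a superset of
#'   every site already on any pool of that protein.
#' @return the updated, validated [MapModel-class].
#' @examples
#' m <- propagateStateVariables(buildFixture("acsn_raf1_stateless"),
#'                              "P04049", "S338")
#' stateSignature(pools(m)$raf1)
#' @export
propagateStateVariables <- function(model, proteinKey, universe) {
  universe <- sort(unique(as.character(universe)))
  poolsL <- model@pools
  for (id in names(poolsL)) {
    p <- poolsL[[id]]
    if (!identical(p@proteinKey, proteinKey)) next
    have <- names(p@state)
    missing <- setdiff(have, universe)
    if (length(missing))
      stop(sprintf("universe for %s is missing existing site(s) %s on pool '%s'; refusing to lose information",
                   proteinKey, paste(missing, collapse = ", "), id),
           call. = FALSE)
    newState <- stats::setNames(rep(NA_character_, length(universe)),
                                universe)
    newState[have] <- p@state
    p@state <- newState[order(names(newState))]
    poolsL[[id]] <- p
  }
  out <- model
  out@pools <- poolsL
  validateMap(out)
}

#' Replace a generic pool by its specific members
#'
#' The semiautomatic generic-to-specific replacement: the generic pool is
#' removed and one specific pool per annotated member is created (state and
#' compartment copied). Under policy `duplicate_processes`, every complex
#' containing the generic pool and every process touching it (or a cloned
#' complex) is cloned once per member, substituting the member uniformly;
#' replacing several generics in turn therefore fans processes out
#' cartesian-wise. Policy `keep_single_member` is only legal for a
#' single-member generic and rewrites the pool in place. The fan-out is
#' recorded on the returned model in `attr(model, "transformLog")`.
#'
#' @param model a [MapModel-class].
#' @param genericPoolId pool id of a generic pool with annotated members.
#' @param policy `"duplicate_processes"` (default) or
#'   `"keep_single_member"`.
#' @return the transformed, validated [MapModel-class].
#' @export
replaceGenericWithSpecific <- function(model, genericPoolId,
                                       policy = c("duplicate_processes",
                                                  "keep_single_member")) {
  policy <- match.arg(policy)
  g <- model@pools[[genericPoolId]]
  if (is.null(g) || !g@isGeneric)
    stop(sprintf("'%s' is not a generic protein pool", genericPoolId),
         call. = FALSE)
  if (!length(g@members))
    stop(sprintf("generic pool '%s' has no annotated members", genericPoolId),
         call. = FALSE)
  log <- attr(model, "transformLog") %||% character()

  if (policy == "keep_single_member") {
    if (length(g@members) != 1L)
      stop("policy 'keep_single_member' requires exactly one member",
           call. = FALSE)
    mem <- g@members
    poolsL <- model@pools
    poolsL[[genericPoolId]] <- ProteinPool(
      g@poolId, label = mem, proteinKey = mem, state = g@state,
      compartment = g@compartment)
    out <- model
    out@pools <- poolsL
    attr(out, "transformLog") <- c(log, sprintf(
      "replace_generic %s -> %s (keep_single_member)", genericPoolId, mem))
    return(validateMap(out))
  }

  members <- g@members
  memberPoolId <- stats::setNames(paste0(genericPoolId, "_", members),
                                  members)
  newPools <- lapply(members, function(mem)
    ProteinPool(memberPoolId[[mem]], label = mem, proteinKey = mem,
                state = g@state, compartment = g@compartment))

  ## complexes containing the generic are cloned per member
  cxTouched <- names(model@complexes)[vapply(model@complexes, function(cx)
    genericPoolId %in% cx@componentIds, logical(1))]
  newCxs <- list(); cxCloneId <- list()
  for (cid in names(model@complexes)) {
    cx <- model@complexes[[cid]]
    if (!cid %in% cxTouched) {
      newCxs[[cid]] <- cx
    } else {
      cxCloneId[[cid]] <- stats::setNames(paste0(cid, "_", members), members)
      for (mem in members) {
        comp <- cx@componentIds
        comp[comp == genericPoolId] <- memberPoolId[[mem]]
        newCxs[[cxCloneId[[cid]][[mem]]]] <-
          ComplexPool(cxCloneId[[cid]][[mem]], comp, cx@compartment)
      }
    }
  }

  touchedIds <- c(genericPoolId, cxTouched)
  substInto <- function(ids, mem) {
    ids[ids == genericPoolId] <- memberPoolId[[mem]]
    for (cid in cxTouched) ids[ids == cid] <- cxCloneId[[cid]][[mem]]
    ids
  }
  newPrs <- list(); fanned <- 0L
  for (pid in names(model@processes)) {
    pr <- model@processes[[pid]]
    refs <- c(pr@reactants, pr@products, pr@modulators$pool)
    if (!any(refs %in% touchedIds)) {
      newPrs[[pid]] <- pr
      next
    }
    fanned <- fanned + 1L
    for (mem in members) {
      mods <- pr@modulators
      mods$pool <- substInto(mods$pool, mem)
      npid <- paste0(pid, "_", mem)
      newPrs[[npid]] <- Process(npid,
                                reactants = substInto(pr@reactants, mem),
                                products = substInto(pr@products, mem),
                                modulators = mods, kind = pr@kind)
    }
  }

  poolsL <- model@pools[names(model@pools) != genericPoolId]
  poolsL <- c(poolsL, stats::setNames(newPools, memberPoolId))
  out <- MapModel(model@mapName, pools = unname(poolsL),
                  complexes = unname(newCxs), processes = unname(newPrs),
                  compartments = model@compartments,
                  provenance = model@provenance)
  attr(out, "transformLog") <- c(log, sprintf(
    "replace_generic %s -> {%s}: %d process(es) fanned out x%d",
    genericPoolId, paste(members, collapse = ","), fanned, length(members)))
  validateMap(out)
}

#' Replace every annotated generic pool of a map
#'
#' Applies [replaceGenericWithSpecific()] repeatedly until no generic pool
#' with annotated members remains. Unannotated generics are left in place.
#'
#' @param model a [MapModel-class].
#' @return the transformed model, with the accumulated transformation log.
#' @export
replaceAllGenerics <- function(model) {
  repeat {
    gid <- NULL
    for (p in model@pools)
      if (p@isGeneric && length(p@members)) { gid <- p@poolId; break }
    if (is.null(gid)) return(model)
    model <- replaceGenericWithSpecific(model, gid)
  }
}

#' MergeReport: outcome of a lint-guarded map merge
#'
#' @slot success whether a merged model was produced.
#' @slot model the merged [MapModel-class] (only when successful).
#' @slot blocking findings that blocked (or, after harmonization, were
#'   resolved before) the merge.
#' @slot postLint findings of the within-map lints on the merged model.
#' @slot log applied-transformation log.
#' @aliases MergeReport-class
#' @exportClass MergeReport
setClass("MergeReport",
  representation(success = "logical", model = "ANY", blocking = "data.frame",
                 postLint = "data.frame", log = "character"))

#' @describeIn MergeReport-class compact display
#' @param object a MergeReport
setMethod("show", "MergeReport", function(object) {
  cat(sprintf("MergeReport: %s; %d blocking finding(s); %d log entr%s\n",
              if (object@success) "merged" else "FAILED",
              nrow(object@blocking), length(object@log),
              if (length(object@log) == 1L) "y" else "ies"))
})

.mergeProcessKey <- function(model, pr) {
  normKind <- if (pr@kind %in% c("association", "dissociation"))
    "generic_process" else pr@kind
  key <- function(ids) paste(sort(vapply(ids, function(id) {
    p <- getPool(model, id)
    if (is(p, "ComplexPool"))
      paste(complexCompositionSignature(model, p, withValues = TRUE),
            collapse = "+")
    else .poolFullKey(p)
  }, character(1))), collapse = "&")
  paste(normKind, key(pr@reactants), key(pr@products),
        paste(sort(paste(vapply(pr@modulators$pool, function(id) {
          p <- getPool(model, id)
          if (is(p, "ComplexPool"))
            paste(complexCompositionSignature(model, p, withValues = TRUE),
                  collapse = "+")
          else .poolFullKey(p)
        }, character(1)), pr@modulators$class)), collapse = "&"),
        sep = " :: ")
}

#' Merge maps, guarded by the composability lints
#'
#' Runs the state-signature and generic/specific lints over the input
#' maps. If blocking findings exist (error- or warning-severity) and
#' `autoHarmonize` is off, the merge fails and the report carries the
#' findings — never a silent partial merge. With `autoHarmonize`, state
#' variables are first propagated to the per-protein union universe across
#' all maps ([propagateStateVariables()]), optionally followed by
#' generic-to-specific replacement, and the merge proceeds. Entities are
#' identified across maps by protein key plus full state (pools) and by
#' composition signature (complexes); processes deduplicate on kind
#' (association/dissociation normalized to a generic process), role-tagged
#' participant identities and modulators. The merged model is validated and
#' the within-map lints must report no error-severity findings for the
#' merge to succeed.
#'
#' @param models list of two or more [MapModel-class] objects.
#' @param autoHarmonize apply state-variable propagation (and optionally
#'   generic replacement) instead of failing on blocking findings.
#' @param replaceGenerics with `autoHarmonize`, also replace annotated
#'   generic pools by their members before merging.
#' @param mergedName name of the merged map; default joins the input names
#'   with " + ".
#' @return a [MergeReport-class].
#' @examples
#' rep <- mergeMaps(list(buildFixture("acsn_canonical", "A"),
#'                       buildFixture("acsn_canonical", "B")))
#' rep@success
#' @export
mergeMaps <- function(models, autoHarmonize = FALSE,
                      replaceGenerics = FALSE, mergedName = NULL) {
  stopifnot(length(models) >= 2L)
  models <- .asModelList(models)
  log <- character()
  blocking <- rbind(lintStateSignature(models),
                    lintGenericSpecific(models))
  blocking <- blocking[blocking$severity %in% c("error", "warning"), ,
                       drop = FALSE]
  if (nrow(blocking) && !autoHarmonize) {
    return(new("MergeReport", success = FALSE, model = NULL,
               blocking = blocking, postLint = .emptyFindings(),
               log = "merge blocked: harmonization required"))
  }
  if (autoHarmonize) {
    ## Replace generics before computing state universes: member pools
    ## inherit the generic's state, and only after replacement do they share
    ## identity keys with specific pools in the other maps, so the union
    ## universe actually unifies them.
    if (replaceGenerics) {
      for (i in seq_along(models)) {
        models[[i]] <- replaceAllGenerics(models[[i]])
        log <- c(log, attr(models[[i]], "transformLog") %||% character())
      }
    }
    ## union state-variable universe per protein across all maps
    uni <- list()
    for (m in models) for (p in m@pools)
      uni[[p@proteinKey]] <- union(uni[[p@proteinKey]], names(p@state))
    for (i in seq_along(models)) {
      keys <- unique(vapply(models[[i]]@pools, function(p) p@proteinKey,
                            character(1)))
      for (k in keys) {
        before <- models[[i]]
        models[[i]] <- propagateStateVariables(models[[i]], k,
                                               uni[[k]] %||% character())
        if (!identical(before@pools, models[[i]]@pools))
          log <- c(log, sprintf("propagate %s in '%s' to {%s}", k,
                                mapName(models[[i]]),
                                paste(sort(uni[[k]]), collapse = ",")))
      }
    }
  }

  nm <- mergedName %||% paste(vapply(models, mapName, character(1)),
                              collapse = " + ")
  poolIdx <- list(); cxIdx <- list(); prIdx <- list()
  pools <- list(); cxs <- list(); prs <- list()
  nPool <- 0L; nCx <- 0L
  for (m in models) {
    idMap <- character()
    for (p in m@pools) {
      k <- .poolFullKey(p)
      if (is.null(poolIdx[[k]])) {
        nPool <- nPool + 1L
        nid <- sprintf("mpool%03d", nPool)
        poolIdx[[k]] <- nid
        q <- p; q@poolId <- nid
        pools[[nid]] <- q
      }
      idMap[[p@poolId]] <- poolIdx[[k]]
    }
    for (cx in m@complexes) {
      k <- paste(c(complexCompositionSignature(m, cx, withValues = TRUE),
                   cx@compartment), collapse = "+")
      if (is.null(cxIdx[[k]])) {
        nCx <- nCx + 1L
        nid <- sprintf("mcx%03d", nCx)
        cxIdx[[k]] <- nid
        cxs[[nid]] <- ComplexPool(nid,
                                  unname(idMap[cx@componentIds]),
                                  cx@compartment)
      }
      idMap[[cx@poolId]] <- cxIdx[[k]]
    }
    for (pr in m@processes) {
      k <- .mergeProcessKey(m, pr)
      if (is.null(prIdx[[k]])) {
        nid <- sprintf("mproc%03d", length(prs) + 1L)
        prIdx[[k]] <- nid
        mods <- pr@modulators
        mods$pool <- unname(idMap[mods$pool])
        prs[[nid]] <- Process(nid,
                              reactants = unname(idMap[pr@reactants]),
                              products = unname(idMap[pr@products]),
                              modulators = mods, kind = pr@kind)
      }
    }
  }
  merged <- MapModel(nm, pools = unname(pools), complexes = unname(cxs),
                     processes = unname(prs),
                     compartments = unique(unlist(lapply(models,
                                                         compartments))),
                     provenance = "merge")
  validateMap(merged)
  post <- rbind(lintStateSignature(list(merged)),
                lintGenericSpecific(list(merged)))
  success <- !any(post$severity == "error")
  new("MergeReport", success = success,
      model = if (success) merged else NULL,
      blocking = blocking, postLint = post,
      log = c(log, sprintf("merged %d maps into '%s'", length(models), nm)))
}
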