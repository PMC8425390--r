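#' @include fixtures.R
NULL

#' Specification of a seeded random PD map
#'
#' Controls the size and composition of a randomly generated process
#' description map used as oracle substrate: every catalyzed
#' phosphorylation the generator plants is recorded as ground truth, so
#' extraction can be checked exactly.
#'
#' @param seed integer seed; the same spec always yields the same map.
#' @param nProteins number of specific proteins.
#' @param nGeneric number of generic group pools (members drawn from the
#'   specific proteins).
#' @param maxStatesPerProtein maximum number of state variables per protein.
#' @param nComplexes number of background complexes.
#' @param nProcesses total number of processes.
#' @param pPhospho fraction (in expectation) of processes that are planted
#'   catalyzed phosphorylations.
#' @param pInComplex fraction of planted phosphorylations whose target sits
#'   inside a complex.
#' @return a `RandomMapSpec` list.
#' @export
randomMapSpec <- function(seed = 1L, nProteins = 6L, nGeneric = 1L,
                          maxStatesPerProtein = 3L, nComplexes = 2L,
                          nProcesses = 10L, pPhospho = 0.5,
                          pInComplex = 0.25) {
  spec <- list(seed = as.integer(seed), nProteins = as.integer(nProteins),
               nGeneric = as.integer(nGeneric),
               maxStatesPerProtein = as.integer(maxStatesPerProtein),
               nComplexes = as.integer(nComplexes),
               nProcesses = as.integer(nProcesses),
               pPhospho = pPhospho, pInComplex = pInComplex)
  with(spec, {
    stopifnot(nProteins >= 1, nGeneric >= 0, maxStatesPerProtein >= 1,
              nComplexes >= 0, nProcesses >= 0,
              pPhospho >= 0, pPhospho <= 1,
              pInComplex >= 0, pInComplex <= 1)
  })
  if (spec$pInComplex > 0 && spec$nComplexes == 0)
    stop("infeasible spec: pInComplex > 0 requires nComplexes > 0",
         call. = FALSE)
  class(spec) <- "RandomMapSpec"
  spec
}

#' Generate a seeded random PD map with embedded ground truth
#'
#' Builds a validated random [MapModel-class] containing planted catalyzed
#' phosphorylation processes (free-protein and in-complex), plus
#' non-extractable background processes (associations and uncatalyzed or
#' non-phospho transitions). All pools of a protein share one
#' state-variable universe, so generated maps are self-consistent under the
#' "once a variable, always a variable" rule.
#'
#' @param spec a [randomMapSpec()].
#' @return a list with elements `model` (the [MapModel-class]) and `truth`
#'   (data.frame of planted events: kinase, target, site, map, mode,
#'   processId).
#' @examples
#' gt <- generateRandomMap(randomMapSpec(seed = 42))
#' nrow(gt$truth)
#' @export
generateRandomMap <- function(spec) {
  stopifnot(inherits(spec, "RandomMapSpec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)

  mapNm <- sprintf("random-map-%d", spec$seed)
  keys <- sprintf("PR%03d", seq_len(spec$nProteins))
  ## fixed per-protein state-variable universe
  siteUniverse <- lapply(keys, function(k) {
    n <- sample.int(spec$maxStatesPerProtein, 1L)
    sort(paste0(sample(c("S", "T", "Y"), n, replace = TRUE),
                sample(50:700, n)))
  })
  names(siteUniverse) <- keys

  pools <- list(); poolN <- 0L
  addPool <- function(label, key, values, isGeneric = FALSE,
                      members = character()) {
    poolN <<- poolN + 1L
    id <- sprintf("sp%03d", poolN)
    pools[[id]] <<- ProteinPool(id, label, proteinKey = key,
                                isGeneric = isGeneric, members = members,
                                state = values)
    id
  }
  baseState <- function(key) stateVariables(siteUniverse[[key]])

  ## one resting pool per protein
  basePoolOf <- character()
  for (k in keys) basePoolOf[[k]] <- addPool(k, k, baseState(k))
  for (g in seq_len(spec$nGeneric)) {
    mem <- sort(sample(keys, min(2L, spec$nProteins)))
    addPool(sprintf("GEN%d", g), sprintf("GEN%d", g), stateVariables(),
            isGeneric = TRUE, members = mem)
  }

  cxs <- list(); cxN <- 0L
  addComplex <- function(componentIds) {
    cxN <<- cxN + 1L
    id <- sprintf("cx%03d", cxN)
    cxs[[id]] <<- ComplexPool(id, componentIds)
    id
  }
  for (i in seq_len(spec$nComplexes)) {
    sz <- sample(2:3, 1L)
    addComplex(sample(names(pools), sz, replace = TRUE))
  }

  prs <- list(); truth <- list()
  addProcess <- function(pr) prs[[pr@processId]] <<- pr

  for (i in seq_len(spec$nProcesses)) {
    pid <- sprintf("proc%03d", i)
    if (stats::runif(1) < spec$pPhospho) {
      ## planted catalyzed phosphorylation
      tgt <- sample(keys, 1L)
      sites <- siteUniverse[[tgt]]
      gained <- sample(sites, sample.int(min(2L, length(sites)), 1L))
      reacState <- baseState(tgt)
      prodState <- reacState; prodState[gained] <- "P"
      kinKey <- sample(keys, 1L)
      kinId <- basePoolOf[[kinKey]]
      inComplex <- stats::runif(1) < spec$pInComplex
      if (inComplex) {
        other <- sample(basePoolOf, 1L)
        rId <- addPool(tgt, tgt, reacState)
        pId <- addPool(tgt, tgt, prodState)
        rcx <- addComplex(c(other, rId))
        pcx <- addComplex(c(other, pId))
        addProcess(Process(pid, rcx, pcx,
                           stats::setNames("catalysis", kinId)))
        mode <- "in_complex"
      } else {
        rId <- addPool(tgt, tgt, reacState)
        pId <- addPool(tgt, tgt, prodState)
        addProcess(Process(pid, rId, pId,
                           stats::setNames("catalysis", kinId)))
        mode <- "free"
      }
      for (s in sort(gained))
        truth[[length(truth) + 1L]] <- data.frame(
          kinase = kinKey, target = tgt, site = s, map = mapNm,
          mode = mode, processId = pid, stringsAsFactors = FALSE)
    } else {
      ## background noise: association or non-phospho transition
      if (stats::runif(1) < 0.5 && length(names(pools)) >= 2L) {
        parts <- sample(names(pools), 2L)
        cxId <- addComplex(parts)
        addProcess(Process(pid, parts, cxId, kind = "association"))
      } else {
        tgt <- sample(keys, 1L)
        st <- baseState(tgt)
        st2 <- st; st2[[sample(seq_along(st2), 1L)]] <- "x"
        rId <- addPool(tgt, tgt, st)
        pId <- addPool(tgt, tgt, st2)
        addProcess(Process(pid, rId, pId))  # no catalyst: not an event
      }
    }
  }

  model <- MapModel(mapNm, pools = unname(pools), complexes = unname(cxs),
                    processes = unname(prs),
                    provenance = sprintf("random:seed=%d", spec$seed))
  validateMap(model)
  truthDf <- if (length(truth)) do.call(rbind, truth) else
    data.frame(kinase = character(), target = character(),
               site = character(), map = character(), mode = character(),
               processId = character(), stringsAsFactors = FALSE)
  list(model = model, truth = truthDf[do.call(order, truthDf), ,
                                      drop = FALSE])
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}
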