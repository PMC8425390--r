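#' @include harmonize.R
NULL

#' Read a PD map file, dispatching on extension
#'
#' `.json` files are read as the native interchange format, `.xml` / `.sbml`
#' as CellDesigner-flavoured SBML.
#'
#' @param path input file.
#' @param mapName optional map-name override (highest precedence, ahead of
#'   the document's own name and the file stem).
#' @return a validated [MapModel-class].
#' @export
readMapFile <- function(path, mapName = NULL) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
    json = readNativeMap(path, mapName = mapName),
    xml = ,
    sbml = readCellDesignerMap(path, mapName = mapName),
    stop(sprintf("unsupported map file extension '.%s' (%s)", ext, path),
         call. = FALSE))
}

#' Configuration of an audit pipeline run
#'
#' @param inputs character vector of map file paths.
#' @param outDir output directory for the artifacts (created if needed).
#' @param mapNames optional character vector of per-file map-name overrides
#'   (recycled against `inputs`; `NA` keeps the file's own name).
#' @param mode census mode: `"both"`, `"free"` or `"complex"`.
#' @param rules lint rules to run.
#' @param reference canonical-site reference table.
#' @param expandGenerics also emit member-expanded event rows.
#' @param minTotal repeat threshold for the census artifact.
#' @return a `RunConfig` list.
#' @export
pipelineConfig <- function(inputs, outDir, mapNames = NULL, mode = "both",
                           rules = c("STATE_SIGNATURE", "GENERIC_SPECIFIC",
                                     "CANONICAL_SITES", "COMPLEX_VARIANT"),
                           reference = canonicalSiteReference(),
                           expandGenerics = FALSE, minTotal = 2L) {
  stopifnot(mode %in% c("both", "free", "complex"))
  structure(list(inputs = inputs, outDir = outDir, mapNames = mapNames,
                 mode = mode, rules = rules, reference = reference,
                 expandGenerics = expandGenerics,
                 minTotal = as.integer(minTotal)),
            class = "RunConfig")
}

.atomicWrite <- function(writeFun, path) {
  tmp <- paste0(path, ".tmp")
  writeFun(tmp)
  file.rename(tmp, path)
  invisible(path)
}

.writeTsv <- function(df, path) {
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  .atomicWrite(function(p) utils::write.table(
    df, p, sep = "\t", quote = FALSE, row.names = FALSE), path)
}

.findingsToJson <- function(findings) {
  rows <- lapply(seq_len(nrow(findings)), function(i) list(
    rule_id = findings$ruleId[[i]],
    severity = findings$severity[[i]],
    protein_key = findings$proteinKey[[i]],
    pools = as.list(strsplit(findings$pools[[i]], ";", fixed = TRUE)[[1]]),
    maps = as.list(strsplit(findings$maps[[i]], ";", fixed = TRUE)[[1]]),
    message = findings$message[[i]],
    payload = findings$payload[[i]]))
  jsonlite::toJSON(rows, auto_unbox = TRUE, pretty = 2, digits = NA,
                   null = "null")
}

#' Write lint findings as JSON
#'
#' @param findings a findings data.frame from [lintMaps()] or one of the
#'   individual lints.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFindingsJson <- function(findings, path) {
  .atomicWrite(function(p) writeLines(.findingsToJson(findings), p,
                                      useBytes = TRUE), path)
}

#' Run the full audit pipeline
#'
#' Executes read, extract, group, filter, divergence and lint stages over a
#' set of map files and writes the artifacts atomically into the output
#' directory: `events.tsv` (all quadruplets), `census.tsv` (repeated
#' patterns with per-map occurrence), `divergence.json` (repeated patterns
#' represented differently), `findings.json` (lint findings) and `run.log`
#' (per-stage counts). Deterministic for a given configuration.
#'
#' @param config a [pipelineConfig()]; alternatively a list of already
#'   loaded [MapModel-class] objects may be supplied as `config$models`
#'   (used by the programmatic interface and tests).
#' @return a list with `exitCode` (0 clean, 2 lint errors present, 64 usage
#'   error), `artifacts` (named file paths), `counts` (stage counts),
#'   `models`, `events`, `census`, `divergence`, `findings`.
#' @export
runPipeline <- function(config) {
  if (is.null(config$models) &&
      (length(config$inputs) == 0L || !all(file.exists(config$inputs)))) {
    message("usage error: no readable inputs")
    return(list(exitCode = 64L, artifacts = character()))
  }
  models <- config$models %||% lapply(seq_along(config$inputs), function(i) {
    nm <- if (!is.null(config$mapNames)) {
      v <- rep_len(config$mapNames, length(config$inputs))[[i]]
      if (is.na(v)) NULL else v
    } else NULL
    readMapFile(config$inputs[[i]], mapName = nm)
  })
  models <- .asModelList(models)
  for (m in models) validateMap(m)

  events <- do.call(rbind, lapply(models, extractPhosphoEvents,
                                  expandGenerics = config$expandGenerics %||%
                                    FALSE))
  if (is.null(events)) events <- .emptyEvents()
  rownames(events) <- NULL
  if (!identical(config$mode %||% "both", "both")) {
    wanted <- if (config$mode == "free") "free" else "in_complex"
    events <- events[events$mode == wanted, , drop = FALSE]
  }
  census <- groupPatterns(events)
  repeated <- filterRepeated(census, config$minTotal %||% 2L)
  divergence <- findDivergentRepresentations(models)
  findings <- lintMaps(models, rules = config$rules,
                       reference = config$reference %||%
                         canonicalSiteReference())

  counts <- c(maps = length(models), events = nrow(events),
              triplets = nrow(census), repeated = nrow(repeated),
              divergent = sum(divergence$divergent),
              findings = nrow(findings),
              errorFindings = sum(findings$severity == "error"))

  artifacts <- character()
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$outDir, f)
    ev <- events
    names(ev)[names(ev) == "processId"] <- "process_id"
    .writeTsv(ev, out("events.tsv"))
    cs <- repeated
    names(cs)[names(cs) == "nMaps"] <- "n_maps"
    .writeTsv(cs, out("census.tsv"))
    divOut <- divergence
    divOut$evidence <- NULL
    .atomicWrite(function(p) writeLines(jsonlite::toJSON(
      list(groups = divOut,
           evidence = divergence$evidence),
      auto_unbox = TRUE, pretty = 2, digits = NA, null = "null"), p,
      useBytes = TRUE), out("divergence.json"))
    writeFindingsJson(findings, out("findings.json"))
    .atomicWrite(function(p) writeLines(c(
      sprintf("pdlint pipeline run over %d map(s)", counts[["maps"]]),
      sprintf("stage counts: %s",
              paste(sprintf("%s=%d", names(counts), counts),
                    collapse = " "))), p), out("run.log"))
    artifacts <- stats::setNames(
      vapply(c("events.tsv", "census.tsv", "divergence.json",
               "findings.json", "run.log"), out, character(1)),
      c("events", "census", "divergence", "findings", "log"))
  }

  list(exitCode = if (any(findings$severity == "error")) 2L else 0L,
       artifacts = artifacts, counts = counts, models = models,
       events = events, census = census, repeated = repeated,
       divergence = divergence, findings = findings)
}
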