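#' @include AllClasses.R AllGenerics.R
NULL

#' Default protein alias table for the MAPK cascade
#'
#' Maps display names and gene symbols of the core RAS-RAF-MEK-ERK proteins
#' (plus the SEF/IL17RD adaptor) to their UniProt primary accessions, so
#' that e.g. "MEK1" and "MAP2K1" resolve to the same identity key Q02750,
#' and "MAPK1" resolves to ERK2's P28482. Labels of generic family pools
#' ("MEK", "ERK", "RAF", "RAS") are deliberately absent: a generic group is
#' not any single accession.
#'
#' @return named character vector, synonym (upper case) -> identity key.
#' @examples
#' defaultAliasTable()[["MAP2K1"]]
#' @export
defaultAliasTable <- function() {
  c(
    MEK1 = "Q02750", MAP2K1 = "Q02750",
    MEK2 = "P36507", MAP2K2 = "P36507",
    ERK1 = "P27361", MAPK3 = "P27361",
    ERK2 = "P28482", MAPK1 = "P28482",
    RAF1 = "P04049", CRAF = "P04049",
    BRAF = "P15056",
    ARAF = "P10398",
    SEF = "Q8NFM7", IL17RD = "Q8NFM7",
    KSR1 = "Q8IVT5",
    YWHAB = "P31946"
  )
}

#' Normalize a protein label to an identity key
#'
#' Identity precedence: UniProt primary accession (first of the supplied
#' accessions, sorted) > alias-table hit on the label > upper-cased trimmed
#' label. The function is total, deterministic and idempotent.
#'
#' @param label display name (non-empty).
#' @param uniprotIds character vector of UniProt accessions (may be empty).
#' @param aliasTable named character vector mapping synonyms to keys; see
#'   [defaultAliasTable].
#' @return a single identity key string.
#' @examples
#' normalizeProteinIdentity("MEK1", "Q02750")   # "Q02750"
#' normalizeProteinIdentity("MAPK1", character()) # "P28482"
#' normalizeProteinIdentity("novelProtX", character()) # "NOVELPROTX"
#' @export
normalizeProteinIdentity <- function(label, uniprotIds = character(),
                                     aliasTable = defaultAliasTable()) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  ids <- sort(unique(uniprotIds[nzchar(uniprotIds)]))
  if (length(ids)) return(ids[[1L]])
  key <- toupper(trimws(label))
  hit <- unname(aliasTable[match(key, names(aliasTable))])
  if (!is.na(hit)) hit else key
}

#' @rdname stateSignature
setMethod("stateSignature", "ProteinPool", function(pool) {
  sort(unique(names(pool@state)))
})

## Full per-pool signature including values; used wherever two pools must be
## compared as "same entity in the same state" (complex matching, merging).
.stateString <- function(pool) {
  st <- pool@state
  if (!length(st)) return("")
  st <- st[order(names(st))]
  paste(sprintf("%s=%s", names(st), ifelse(is.na(st), "", st)),
        collapse = ";")
}

.poolFullKey <- function(pool) {
  paste0(pool@proteinKey,
         if (pool@isGeneric)
           sprintf("{%s}", paste(pool@members, collapse = ",")) else "",
         "@", .stateString(pool), "|", pool@compartment)
}

#' Composition signature of a complex
#'
#' An order-independent multiset description of a complex: one
#' `(proteinKey, state signature)` entry per component, sorted. Two
#' complexes with identical components in identical states compare equal
#' regardless of construction order.
#'
#' @param model the [MapModel-class] owning the complex (needed to resolve
#'   component pool references).
#' @param cx a [ComplexPool-class] or its pool id.
#' @param withValues include state-variable values (not just sites) in the
#'   per-component signatures. Default `FALSE` per the signature definition.
#' @return sorted character vector with one `key[site1,site2]` entry per
#'   component (values appended when `withValues = TRUE`).
#' @export
complexCompositionSignature <- function(model, cx, withValues = FALSE) {
  if (is.character(cx)) cx <- getPool(model, cx)
  stopifnot(is(cx, "ComplexPool"))
  entries <- vapply(cx@componentIds, function(id) {
    p <- getPool(model, id)
    if (withValues) paste0(p@proteinKey, "[", .stateString(p), "]")
    else paste0(p@proteinKey, "[",
                paste(stateSignature(p), collapse = ","), "]")
  }, character(1), USE.NAMES = FALSE)
  sort(entries)
}

## Human-readable label for a complex: sorted component protein keys.
.complexLabel <- function(model, cx) {
  if (is.character(cx)) cx <- getPool(model, cx)
  keys <- vapply(cx@componentIds,
                 function(id) getPool(model, id)@proteinKey, character(1))
  paste0("complex(", paste(sort(keys), collapse = ","), ")")
}

## Identity-key set of an entity pool: a specific protein contributes its
## key, a generic pool its member keys (or its own key when unannotated),
## a complex the union over its components.
.identityKeys <- function(model, id) {
  p <- getPool(model, id)
  if (is(p, "ComplexPool")) {
    sort(unique(unlist(lapply(p@componentIds,
                              function(i) .identityKeys(model, i)))))
  } else if (p@isGeneric) {
    if (length(p@members)) p@members else p@proteinKey
  } else {
    p@proteinKey
  }
}

## Recorded name of a pool for quadruplets: protein_key for specific pools,
## the (normalized) generic label for generic pools, a composition label for
## complexes.
.recordedName <- function(model, id) {
  p <- getPool(model, id)
  if (is(p, "ComplexPool")) .complexLabel(model, p)
  else p@proteinKey
}
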