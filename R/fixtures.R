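#' @include identity.R
NULL

## Shorthand constructors used by the preset builders.
.pp <- function(id, label, sites = character(), values = NA_character_, ...) {
  ProteinPool(id, label, state = stateVariables(sites, values), ...)
}

## MEK1/MEK2 and ERK1/ERK2 member key sets used throughout the presets.
.MEK_MEMBERS <- c("Q02750", "P36507")
.ERK_MEMBERS <- c("P27361", "P28482")
.RAF_MEMBERS <- c("P04049", "P10398", "P15056")

## Six literature-canonical RAF1 regulatory phosphosites used as
## placeholders for the detailed RAF1 representation (the counts, six
## residues plus one named flag, are the contract; the tokens are
## configurable data, not asserted biology).
.RAF1_DETAILED_SITES <- c("S259", "S289", "S296", "S301", "S338", "S621")

.PRESET_DEFAULT_NAMES <- c(
  acsn_canonical = "Adaptive Immunity",
  acsn_raf1_stateless = "Regulated Cell Death",
  acsn_cell_survival_sef = "Cell Survival",
  acsn_emt_raf1_detailed = "EMT and Senescence",
  panther_interleukin = "Interleukin Signalling Pathway",
  panther_fgf = "FGF Signalling Pathway",
  panther_bcell_complexes = "B Cell Activation",
  reactome_raf_map_kinase = "RAF-MAP Kinase Cascade",
  reactome_raf_independent = "RAF-independent MAPK1-3 Activation",
  reactome_l1cam_mek1 = "L1CAM Interactions",
  generic_mek_dimer = "MEK Dimer Fragment")

#' List the available fixture presets
#'
#' Deterministic, duplicate-free list of synthetic RAS-RAF-MEK-ERK map
#' fragments in the styles of the ACSN, PANTHER and Reactome databases.
#'
#' @return character vector of preset ids.
#' @examples
#' listPresets()
#' @export
listPresets <- function() names(.PRESET_DEFAULT_NAMES)

.buildAcsnCanonical <- function(nm) {
  MapModel(nm, provenance = "acsn_canonical",
    pools = list(
      .pp("ras", "RAS"),
      .pp("raf1_i", "RAF1", "activity"),
      .pp("raf1_a", "RAF1", "activity", "P"),
      .pp("mek_i", "MEK", "activity", isGeneric = TRUE,
          members = .MEK_MEMBERS),
      .pp("mek_a", "MEK", "activity", "P", isGeneric = TRUE,
          members = .MEK_MEMBERS),
      .pp("erk_i", "ERK", "activity", isGeneric = TRUE,
          members = .ERK_MEMBERS),
      .pp("erk_a", "ERK", "activity", "P", isGeneric = TRUE,
          members = .ERK_MEMBERS)),
    processes = list(
      Process("p_raf", "raf1_i", "raf1_a", c(ras = "catalysis")),
      Process("p_mek", "mek_i", "mek_a", c(raf1_a = "catalysis")),
      Process("p_erk", "erk_i", "erk_a", c(mek_a = "catalysis"))))
}

.buildAcsnStateless <- function(nm) {
  MapModel(nm, provenance = "acsn_raf1_stateless",
    pools = list(.pp("raf1", "RAF1"), .pp("ywhab", "YWHAB")),
    complexes = list(ComplexPool("cx_raf_1433", c("raf1", "ywhab"))),
    processes = list(
      Process("p_assoc", c("raf1", "ywhab"), "cx_raf_1433",
              kind = "association")))
}

.buildAcsnCellSurvivalSef <- function(nm) {
  MapModel(nm, provenance = "acsn_cell_survival_sef",
    pools = list(
      .pp("braf", "BRAF"),
      .pp("mek_i", "MEK", "activity", isGeneric = TRUE,
          members = .MEK_MEMBERS),
      .pp("mek_a", "MEK", "activity", "P", isGeneric = TRUE,
          members = .MEK_MEMBERS),
      .pp("erk_i", "ERK", "activity", isGeneric = TRUE,
          members = .ERK_MEMBERS),
      .pp("erk_a", "ERK", "activity", "P", isGeneric = TRUE,
          members = .ERK_MEMBERS),
      .pp("sef", "SEF")),
    complexes = list(
      ComplexPool("cx_sef_erk_i", c("sef", "erk_i")),
      ComplexPool("cx_sef_erk_a", c("sef", "erk_a"))),
    processes = list(
      Process("p_mek", "mek_i", "mek_a", c(braf = "catalysis")),
      Process("p_erk", "erk_i", "erk_a", c(mek_a = "catalysis")),
      Process("p_erk_sef", "cx_sef_erk_i", "cx_sef_erk_a",
              c(mek_a = "catalysis"))))
}

.buildAcsnEmtDetailed <- function(nm) {
  rafSites <- c(.RAF1_DETAILED_SITES, "activity")
  rafActive <- stats::setNames(rep(NA_character_, length(rafSites)), rafSites)
  rafActive[["S338"]] <- "P"; rafActive[["activity"]] <- "active"
  MapModel(nm, provenance = "acsn_emt_raf1_detailed",
    pools = list(
      .pp("ras", "RAS"),
      .pp("raf1_i", "RAF1", rafSites),
      .pp("raf1_a", "RAF1", names(rafActive), unname(rafActive)),
      .pp("mek1_i", "MEK1", c("S218", "S222")),
      .pp("mek1_a", "MEK1", c("S218", "S222"), "P"),
      .pp("mek2_i", "MEK2", c("S222", "S226")),
      .pp("mek2_a", "MEK2", c("S222", "S226"), "P"),
      .pp("erk1_i", "ERK1", c("T202", "Y204")),
      .pp("erk1_a", "ERK1", c("T202", "Y204"), "P"),
      .pp("erk2_i", "ERK2", c("T185", "Y187")),
      .pp("erk2_a", "ERK2", c("T185", "Y187"), "P")),
    processes = list(
      Process("p_raf", "raf1_i", "raf1_a", c(ras = "catalysis")),
      Process("p_mek1", "mek1_i", "mek1_a", c(raf1_a = "catalysis")),
      Process("p_mek2", "mek2_i", "mek2_a", c(raf1_a = "catalysis")),
      Process("p_erk1", "erk1_i", "erk1_a", c(mek1_a = "catalysis")),
      Process("p_erk2", "erk2_i", "erk2_a", c(mek2_a = "catalysis"))))
}

.buildPantherInterleukin <- function(nm) {
  MapModel(nm, provenance = "panther_interleukin",
    pools = list(
      .pp("ras", "RAS"),
      .pp("raf1_i", "RAF1", "activity"),
      .pp("raf1_a", "RAF1", "activity", "P"),
      .pp("mek_i", "MEK", c("S218", "S222"), isGeneric = TRUE,
          members = .MEK_MEMBERS),
      .pp("mek_a", "MEK", c("S218", "S222"), "P", isGeneric = TRUE,
          members = .MEK_MEMBERS),
      .pp("erk_i", "ERK", c("T202", "Y204"), isGeneric = TRUE,
          members = .ERK_MEMBERS),
      .pp("erk_a", "ERK", c("T202", "Y204"), "P", isGeneric = TRUE,
          members = .ERK_MEMBERS)),
    processes = list(
      Process("p_raf", "raf1_i", "raf1_a", c(ras = "catalysis")),
      Process("p_mek", "mek_i", "mek_a", c(raf1_a = "catalysis")),
      Process("p_erk", "erk_i", "erk_a", c(mek_a = "catalysis"))))
}

.buildPantherFgf <- function(nm) {
  MapModel(nm, provenance = "panther_fgf",
    pools = list(
      .pp("ras", "RAS"),
      .pp("raf_i", "RAF", "activity", isGeneric = TRUE,
          members = .RAF_MEMBERS),
      .pp("raf_a", "RAF", "activity", "P", isGeneric = TRUE,
          members = .RAF_MEMBERS),
      .pp("mek_i", "MEK", "activity", isGeneric = TRUE,
          members = .MEK_MEMBERS),
      .pp("mek_a", "MEK", "activity", "P", isGeneric = TRUE,
          members = .MEK_MEMBERS),
      .pp("erk_i", "ERK", "activity", isGeneric = TRUE,
          members = .ERK_MEMBERS),
      .pp("erk_a", "ERK", "activity", "P", isGeneric = TRUE,
          members = .ERK_MEMBERS)),
    processes = list(
      Process("p_raf", "raf_i", "raf_a", c(ras = "catalysis")),
      Process("p_mek", "mek_i", "mek_a", c(raf_a = "catalysis")),
      Process("p_erk", "erk_i", "erk_a", c(mek_a = "catalysis"))))
}

.buildPantherBcell <- function(nm) {
  MapModel(nm, provenance = "panther_bcell_complexes",
    pools = list(
      .pp("ras", "RAS"),
      .pp("raf", "RAF", isGeneric = TRUE, members = .RAF_MEMBERS),
      .pp("mek_i", "MEK", "activity", isGeneric = TRUE,
          members = .MEK_MEMBERS),
      .pp("mek_a", "MEK", "activity", "P", isGeneric = TRUE,
          members = .MEK_MEMBERS),
      .pp("erk_i", "ERK", "activity", isGeneric = TRUE,
          members = .ERK_MEMBERS),
      .pp("erk_a", "ERK", "activity", "P", isGeneric = TRUE,
          members = .ERK_MEMBERS)),
    complexes = list(
      ComplexPool("cx_ras_raf", c("ras", "raf")),
      ComplexPool("cx_raf_mek_i", c("raf", "mek_i")),
      ComplexPool("cx_raf_mek_a", c("raf", "mek_a"))),
    processes = list(
      Process("p_a1", c("ras", "raf"), "cx_ras_raf", kind = "association"),
      Process("p_a2", c("raf", "mek_i"), "cx_raf_mek_i",
              kind = "association"),
      Process("p_mek", "cx_raf_mek_i", "cx_raf_mek_a",
              c(cx_ras_raf = "catalysis")),
      Process("p_erk", "erk_i", "erk_a", c(cx_raf_mek_a = "catalysis"))))
}

.buildReactomeRafMapKinase <- function(nm) {
  MapModel(nm, provenance = "reactome_raf_map_kinase",
    pools = list(
      .pp("ras", "RAS"),
      .pp("raf_i", "RAF", "activity", isGeneric = TRUE,
          members = .RAF_MEMBERS),
      .pp("raf_a", "RAF", "activity", "P", isGeneric = TRUE,
          members = .RAF_MEMBERS),
      .pp("mek_i", "MEK", c("S218", "S222"), isGeneric = TRUE,
          members = .MEK_MEMBERS),
      .pp("mek_a", "MEK", c("S218", "S222"), "P", isGeneric = TRUE,
          members = .MEK_MEMBERS),
      .pp("erk1_i", "ERK1", c("T202", "Y204")),
      .pp("erk1_a", "ERK1", c("T202", "Y204"), "P"),
      .pp("erk2_i", "ERK2", c("T185", "Y187")),
      .pp("erk2_a", "ERK2", c("T185", "Y187"), "P")),
    complexes = list(
      ComplexPool("cx_mekdim_i", c("mek_i", "mek_i")),
      ComplexPool("cx_mekdim_a", c("mek_a", "mek_a"))),
    processes = list(
      Process("p_raf", "raf_i", "raf_a", c(ras = "catalysis")),
      Process("p_mekdim", "cx_mekdim_i", "cx_mekdim_a",
              c(raf_a = "catalysis")),
      Process("p_erk1", "erk1_i", "erk1_a", c(cx_mekdim_a = "catalysis")),
      Process("p_erk2", "erk2_i", "erk2_a", c(cx_mekdim_a = "catalysis"))))
}

.buildReactomeRafIndependent <- function(nm) {
  MapModel(nm, provenance = "reactome_raf_independent",
    pools = list(
      .pp("mek1_a", "MEK1", c("S218", "S222"), "P"),
      .pp("erk1_i", "ERK1", c("T202", "Y204")),
      .pp("erk1_a", "ERK1", c("T202", "Y204"), "P"),
      .pp("erk2_i", "ERK2", c("T185", "Y187")),
      .pp("erk2_a", "ERK2", c("T185", "Y187"), "P")),
    processes = list(
      Process("p_erk1", "erk1_i", "erk1_a", c(mek1_a = "catalysis")),
      Process("p_erk2", "erk2_i", "erk2_a", c(mek1_a = "catalysis"))))
}

.buildReactomeL1camMek1 <- function(nm) {
  MapModel(nm, provenance = "reactome_l1cam_mek1",
    pools = list(
      .pp("mek1_4p", "MEK1", c("S218", "S222", "T286", "T292"), "P"),
      .pp("mek1_2p", "MEK1", c("T286", "T292"), "P")))
}

.buildGenericMekDimer <- function(nm) {
  MapModel(nm, provenance = "generic_mek_dimer",
    pools = list(.pp("mek", "MEK", isGeneric = TRUE,
                     members = .MEK_MEMBERS)),
    complexes = list(ComplexPool("cx_mek_dimer", c("mek", "mek"))))
}

.PRESET_BUILDERS <- list(
  acsn_canonical = .buildAcsnCanonical,
  acsn_raf1_stateless = .buildAcsnStateless,
  acsn_cell_survival_sef = .buildAcsnCellSurvivalSef,
  acsn_emt_raf1_detailed = .buildAcsnEmtDetailed,
  panther_interleukin = .buildPantherInterleukin,
  panther_fgf = .buildPantherFgf,
  panther_bcell_complexes = .buildPantherBcell,
  reactome_raf_map_kinase = .buildReactomeRafMapKinase,
  reactome_raf_independent = .buildReactomeRafIndependent,
  reactome_l1cam_mek1 = .buildReactomeL1camMek1,
  generic_mek_dimer = .buildGenericMekDimer)

#' Build a synthetic map fragment preset
#'
#' Each preset is a deterministic, validated reconstruction of one of the
#' RAS-RAF-MEK-ERK pathway fragments the package is designed to audit:
#'
#' * `acsn_canonical` — the canonical RAS -> RAF1 -> generic MEK -> generic
#'   ERK cascade (RAF1 with a single `activity` state variable; MEK/ERK
#'   generic with annotated members). Instantiable under any map name; the
#'   same fragment is reused by several ACSN maps.
#' * `acsn_raf1_stateless` — RAF1 with no state variables, embedded in an
#'   unrelated 14-3-3 association.
#' * `acsn_cell_survival_sef` — canonical MEK/ERK activation plus a
#'   SEF/IL17RD-bound complex variant of the MEK-ERK step.
#' * `acsn_emt_raf1_detailed` — RAF1 with seven state variables (six
#'   residue phosphosites plus one named flag) and specific
#'   MEK1/MEK2/ERK1/ERK2 pools with their activating sites.
#' * `panther_interleukin` / `panther_fgf` — canonical cascades differing
#'   only in phosphosite detail; specific RAF1 in the former, generic RAF
#'   in the latter.
#' * `panther_bcell_complexes` — small-complex (RAS-RAF, RAF-MEK) variant
#'   of the cascade.
#' * `reactome_raf_map_kinase` — generic RAF (ARAF/BRAF/RAF1) activating a
#'   generic MEK1/2 dimer; ERK phosphosites consistent with
#'   `reactome_raf_independent`.
#' * `reactome_raf_independent` — MEK1-driven ERK activation without RAF.
#' * `reactome_l1cam_mek1` — two MEK1 entities phosphorylated at
#'   S218/S222/T286/T292 and at T286/T292 (a deliberate within-map
#'   state-signature conflict).
#' * `generic_mek_dimer` — a single dimer complex of a generic MEK pool.
#'
#' @param presetId one of [listPresets()].
#' @param mapName optional map-name override (the default is a per-preset
#'   pathway name).
#' @return a validated [MapModel-class].
#' @examples
#' m <- buildFixture("acsn_emt_raf1_detailed")
#' stateSignature(pools(m)$raf1_i)
#' @export
buildFixture <- function(presetId, mapName = NULL) {
  builder <- .PRESET_BUILDERS[[presetId]]
  if (is.null(builder))
    stop(sprintf("unknown preset '%s'; valid presets: %s", presetId,
                 paste(listPresets(), collapse = ", ")), call. = FALSE)
  nm <- mapName %||% .PRESET_DEFAULT_NAMES[[presetId]]
  validateMap(builder(nm))
}

#' Build the ACSN preset collection
#'
#' The canonical fragment instantiated under the three ACSN map names that
#' reuse it, plus the stateless-RAF1, SEF-variant and detailed-RAF1
#' fragments — six maps in total.
#'
#' @return named list of [MapModel-class] objects.
#' @export
acsnPresetSet <- function() {
  canonicalNames <- c("Adaptive Immunity", "Innate Immunity",
                      "Cancer-Associated Fibroblasts")
  maps <- c(
    lapply(canonicalNames, function(nm) buildFixture("acsn_canonical", nm)),
    list(buildFixture("acsn_raf1_stateless"),
         buildFixture("acsn_cell_survival_sef"),
         buildFixture("acsn_emt_raf1_detailed")))
  stats::setNames(maps, vapply(maps, mapName, character(1)))
}

#' @rdname acsnPresetSet
#' @export
pantherPresetSet <- function() {
  ids <- c("panther_interleukin", "panther_fgf", "panther_bcell_complexes")
  maps <- lapply(ids, buildFixture)
  stats::setNames(maps, vapply(maps, mapName, character(1)))
}

#' @rdname acsnPresetSet
#' @export
reactomePresetSet <- function() {
  ids <- c("reactome_raf_map_kinase", "reactome_raf_independent",
           "reactome_l1cam_mek1")
  maps <- lapply(ids, buildFixture)
  stats::setNames(maps, vapply(maps, mapName, character(1)))
}
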