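#' @include map-io-native.R
NULL

.SBML_NS <- "http://www.sbml.org/sbml/level2/version4"
.CD_NS <- "http://www.sbml.org/2001/ns/celldesigner"

.xesc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

.KIND_TO_CD <- c(state_transition = "STATE_TRANSITION",
                 association = "HETERODIMER_ASSOCIATION",
                 dissociation = "DISSOCIATION",
                 generic_process = "UNKNOWN_TRANSITION")
.MOD_TO_CD <- c(catalysis = "CATALYSIS",
                stimulation = "PHYSICAL_STIMULATION",
                unknown = "MODULATION")

#' Write a map as CellDesigner-flavoured SBML
#'
#' Serializes a [MapModel-class] to SBML Level 2 XML carrying the
#' CellDesigner 4.x extension namespace, covering the subset this package
#' defines: protein species with modification residues and states
#' (`phosphorylated` for value `"P"`, `empty` for unset, the literal value
#' otherwise), generic proteins (`type="GENERIC"` with a `members`
#' attribute), complex species (composition recorded in a
#' `celldesigner:complexComposition` element), and reactions with
#' reactant/product/modifier lists and modification types
#' (`CATALYSIS`, `PHYSICAL_STIMULATION`). No layout is written.
#'
#' @param model a validated [MapModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCellDesignerMap <- function(model, path) {
  validateMap(model)
  out <- character()
  add <- function(...) out <<- c(out, sprintf(...))

  ## one celldesigner:protein element per distinct protein entity
  protKey <- vapply(model@pools, function(p) {
    paste(p@proteinKey, p@label, p@isGeneric,
          paste(p@members, collapse = ","),
          paste(p@uniprotIds, collapse = ","), sep = "\r")
  }, character(1))
  uprot <- !duplicated(protKey)
  protIds <- stats::setNames(paste0("pr", seq_len(sum(uprot))),
                             protKey[uprot])
  ## residue ids per protein element, spanning the union of sites across
  ## all pools of that protein entity
  protSites <- lapply(split(model@pools, protKey), function(ps) {
    sort(unique(unlist(lapply(ps, function(p) names(p@state)))))
  })

  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<sbml xmlns="%s" xmlns:celldesigner="%s" level="2" version="4">',
      .SBML_NS, .CD_NS)
  add('  <model id="m1" name="%s">', .xesc(model@mapName))
  add('    <annotation>')
  add('      <celldesigner:extension>')
  add('        <celldesigner:listOfProteins>')
  for (k in names(protIds)) {
    ps <- strsplit(k, "\r", fixed = TRUE)[[1]]
    p <- model@pools[[which(protKey == k)[1L]]]
    add(paste0('          <celldesigner:protein id="%s" name="%s" type="%s"',
               ' uniprot="%s" members="%s">'),
        protIds[[k]], .xesc(p@label),
        if (p@isGeneric) "GENERIC" else "PROTEIN",
        .xesc(paste(p@uniprotIds, collapse = " ")),
        .xesc(paste(p@members, collapse = " ")))
    sites <- protSites[[k]]
    if (length(sites)) {
      add('            <celldesigner:listOfModificationResidues>')
      for (i in seq_along(sites))
        add(paste0('              <celldesigner:modificationResidue ',
                   'id="%s_rs%d" name="%s"/>'),
            protIds[[k]], i, .xesc(sites[[i]]))
      add('            </celldesigner:listOfModificationResidues>')
    }
    add('          </celldesigner:protein>')
  }
  add('        </celldesigner:listOfProteins>')
  add('      </celldesigner:extension>')
  add('    </annotation>')
  add('    <listOfCompartments>')
  for (cp in sort(model@compartments))
    add('      <compartment id="%s"/>', .xesc(cp))
  add('    </listOfCompartments>')
  add('    <listOfSpecies>')
  for (p in model@pools[order(names(model@pools))]) {
    k <- protKey[[p@poolId]]
    add('      <species id="%s" name="%s" compartment="%s">',
        .xesc(p@poolId), .xesc(p@label), .xesc(p@compartment))
    add('        <annotation>')
    add('          <celldesigner:extension>')
    add('            <celldesigner:speciesIdentity>')
    add('              <celldesigner:class>PROTEIN</celldesigner:class>')
    add('              <celldesigner:proteinReference>%s</celldesigner:proteinReference>',
        protIds[[k]])
    if (length(p@state)) {
      add('              <celldesigner:state>')
      add('                <celldesigner:listOfModifications>')
      sites <- protSites[[k]]
      for (s in names(p@state)) {
        v <- p@state[[s]]
        cdState <- if (is.na(v)) "empty"
                   else if (identical(v, "P")) "phosphorylated" else v
        add(paste0('                  <celldesigner:modification ',
                   'residue="%s_rs%d" state="%s"/>'),
            protIds[[k]], match(s, sites), .xesc(cdState))
      }
      add('                </celldesigner:listOfModifications>')
      add('              </celldesigner:state>')
    }
    add('            </celldesigner:speciesIdentity>')
    add('          </celldesigner:extension>')
    add('        </annotation>')
    add('      </species>')
  }
  for (cx in model@complexes[order(names(model@complexes))]) {
    add('      <species id="%s" name="%s" compartment="%s">',
        .xesc(cx@poolId), .xesc(cx@poolId), .xesc(cx@compartment))
    add('        <annotation>')
    add('          <celldesigner:extension>')
    add('            <celldesigner:speciesIdentity>')
    add('              <celldesigner:class>COMPLEX</celldesigner:class>')
    add('            </celldesigner:speciesIdentity>')
    add('            <celldesigner:complexComposition components="%s"/>',
        .xesc(paste(cx@componentIds, collapse = " ")))
    add('          </celldesigner:extension>')
    add('        </annotation>')
    add('      </species>')
  }
  add('    </listOfSpecies>')
  if (length(model@processes)) {
    add('    <listOfReactions>')
    for (pr in model@processes[order(names(model@processes))]) {
      add('      <reaction id="%s" reversible="false">', .xesc(pr@processId))
      add('        <annotation>')
      add('          <celldesigner:extension>')
      add('            <celldesigner:reactionType>%s</celldesigner:reactionType>',
          .KIND_TO_CD[[pr@kind]])
      add('          </celldesigner:extension>')
      add('        </annotation>')
      if (length(pr@reactants)) {
        add('        <listOfReactants>')
        for (r in pr@reactants)
          add('          <speciesReference species="%s"/>', .xesc(r))
        add('        </listOfReactants>')
      }
      if (length(pr@products)) {
        add('        <listOfProducts>')
        for (r in pr@products)
          add('          <speciesReference species="%s"/>', .xesc(r))
        add('        </listOfProducts>')
      }
      if (nrow(pr@modulators)) {
        add('        <listOfModifiers>')
        for (i in seq_len(nrow(pr@modulators))) {
          add(paste0('          <modifierSpeciesReference species="%s">',
                     '<annotation><celldesigner:extension>',
                     '<celldesigner:modification type="%s" modifiers="%s"/>',
                     '</celldesigner:extension></annotation>',
                     '</modifierSpeciesReference>'),
              .xesc(pr@modulators$pool[[i]]),
              .MOD_TO_CD[[pr@modulators$class[[i]]]],
              .xesc(pr@modulators$pool[[i]]))
        }
        add('        </listOfModifiers>')
      }
      add('      </reaction>')
    }
    add('    </listOfReactions>')
  }
  add('  </model>')
  add('</sbml>')
  txt <- paste(out, collapse = "\n")
  xml2::read_xml(txt)  # well-formedness check before touching disk
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

.CD_TO_KIND <- stats::setNames(names(.KIND_TO_CD), .KIND_TO_CD)
.CD_TO_MOD <- c(CATALYSIS = "catalysis", UNKNOWN_CATALYSIS = "catalysis",
                PHYSICAL_STIMULATION = "stimulation")

.lookup <- function(tbl, key, default) {
  if (length(key) != 1L || is.na(key) || !key %in% names(tbl)) default
  else tbl[[key]]
}

## XPath over extension elements by local name, robust to whatever prefix a
## producing tool used for the celldesigner namespace.
.cdPath <- function(...) {
  steps <- vapply(c(...), function(s) sprintf("*[local-name()='%s']", s),
                  character(1))
  paste0(".//", paste(steps, collapse = "/"))
}

#' Read a map from CellDesigner-flavoured SBML
#'
#' Parses the SBML L2 + CellDesigner-extension subset written by
#' [writeCellDesignerMap()] (and tolerant of version differences in the
#' extension namespace: elements are matched by local name). Species marked
#' `phosphorylated` at a modification residue yield state variables with
#' value `"P"`; `empty` states yield unset variables. Unsupported species
#' classes (genes, RNAs, small molecules, ...) are skipped with a warning,
#' together with any reaction that references them; nothing is dropped
#' silently.
#'
#' @param path input file path (malformed XML raises a parse error).
#' @param mapName optional override; default is the SBML model `name`
#'   attribute, falling back to the file stem.
#' @return a validated [MapModel-class] with `provenance` set to `path`.
#' @export
readCellDesignerMap <- function(path, mapName = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  modelNode <- xml2::xml_find_first(doc, ".//model")
  if (inherits(modelNode, "xml_missing"))
    stop(sprintf("no <model> element in '%s'", path), call. = FALSE)
  nm <- mapName %||% xml2::xml_attr(modelNode, "name")
  if (is.na(nm) || !nzchar(nm))
    nm <- sub("\\.[^.]*$", "", basename(path))

  ## protein dictionary from the celldesigner extension
  protNodes <- xml2::xml_find_all(doc, .cdPath("listOfProteins", "protein"))
  prot <- list()
  for (pn in protNodes) {
    pid <- xml2::xml_attr(pn, "id")
    rs <- xml2::xml_find_all(pn, .cdPath("modificationResidue"))
    prot[[pid]] <- list(
      name = xml2::xml_attr(pn, "name"),
      generic = identical(xml2::xml_attr(pn, "type"), "GENERIC"),
      uniprot = strsplit(trimws(xml2::xml_attr(pn, "uniprot") %|NA|% ""),
                         "\\s+")[[1]],
      members = strsplit(trimws(xml2::xml_attr(pn, "members") %|NA|% ""),
                         "\\s+")[[1]],
      residues = stats::setNames(xml2::xml_attr(rs, "name"),
                                 xml2::xml_attr(rs, "id")))
  }

  pools <- list(); cxs <- list(); skipped <- character()
  for (sn in xml2::xml_find_all(modelNode, ".//listOfSpecies/species")) {
    sid <- xml2::xml_attr(sn, "id")
    cpt <- xml2::xml_attr(sn, "compartment") %|NA|% "default"
    cls <- xml2::xml_text(xml2::xml_find_first(sn, .cdPath("speciesIdentity", "class")))
    if (identical(cls, "PROTEIN")) {
      ref <- xml2::xml_text(xml2::xml_find_first(
        sn, .cdPath("speciesIdentity", "proteinReference")))
      info <- prot[[ref]]
      if (is.null(info)) {
        warning(sprintf("species '%s': unresolved protein reference '%s'; skipped",
                        sid, ref), call. = FALSE)
        skipped <- c(skipped, sid)
        next
      }
      mods <- xml2::xml_find_all(sn, .cdPath("listOfModifications", "modification"))
      sites <- character(); values <- character()
      for (mn in mods) {
        res <- xml2::xml_attr(mn, "residue")
        st <- xml2::xml_attr(mn, "state")
        site <- .lookup(info$residues, res, NA_character_)
        if (is.na(site)) {
          warning(sprintf("species '%s': unknown residue '%s'; skipped",
                          sid, res), call. = FALSE)
          next
        }
        sites <- c(sites, site)
        values <- c(values,
                    if (is.na(st) || identical(st, "empty")) NA_character_
                    else if (identical(st, "phosphorylated")) "P" else st)
      }
      lbl <- xml2::xml_attr(sn, "name") %|NA|% info$name
      pools[[sid]] <- ProteinPool(
        poolId = sid, label = lbl,
        uniprotIds = info$uniprot[nzchar(info$uniprot)],
        isGeneric = info$generic,
        members = info$members[nzchar(info$members)],
        compartment = cpt, state = stateVariables(sites, values))
    } else if (identical(cls, "COMPLEX")) {
      comp <- xml2::xml_attr(
        xml2::xml_find_first(sn, .cdPath("complexComposition")), "components")
      comps <- strsplit(trimws(comp %|NA|% ""), "\\s+")[[1]]
      if (!length(comps)) {
        warning(sprintf("complex species '%s' without composition; skipped",
                        sid), call. = FALSE)
        skipped <- c(skipped, sid)
        next
      }
      cxs[[sid]] <- ComplexPool(sid, comps, compartment = cpt)
    } else {
      warning(sprintf("species '%s' of unsupported class '%s'; skipped",
                      sid, cls %|NA|% "?"), call. = FALSE)
      skipped <- c(skipped, sid)
    }
  }

  prs <- list()
  for (rn in xml2::xml_find_all(modelNode, ".//listOfReactions/reaction")) {
    rid <- xml2::xml_attr(rn, "id")
    rtype <- xml2::xml_text(xml2::xml_find_first(rn, .cdPath("reactionType")))
    kind <- .lookup(.CD_TO_KIND, rtype, "generic_process")
    reac <- xml2::xml_attr(
      xml2::xml_find_all(rn, "./listOfReactants/speciesReference"), "species")
    prod <- xml2::xml_attr(
      xml2::xml_find_all(rn, "./listOfProducts/speciesReference"), "species")
    modNodes <- xml2::xml_find_all(rn,
      "./listOfModifiers/modifierSpeciesReference")
    modPool <- xml2::xml_attr(modNodes, "species")
    modClass <- vapply(modNodes, function(mn) {
      ty <- xml2::xml_attr(xml2::xml_find_first(mn, .cdPath("modification")),
                           "type")
      .lookup(.CD_TO_MOD, ty, "unknown")
    }, character(1))
    if (any(c(reac, prod, modPool) %in% skipped)) {
      warning(sprintf("reaction '%s' references skipped species; skipped",
                      rid), call. = FALSE)
      next
    }
    prs[[rid]] <- Process(rid, reactants = reac, products = prod,
                          modulators = data.frame(pool = modPool,
                                                  class = modClass,
                                                  stringsAsFactors = FALSE),
                          kind = kind)
  }

  cptIds <- xml2::xml_attr(
    xml2::xml_find_all(modelNode, ".//listOfCompartments/compartment"), "id")
  if (!length(cptIds)) cptIds <- "default"
  model <- MapModel(nm, pools = unname(pools), complexes = unname(cxs),
                    processes = unname(prs), compartments = cptIds,
                    provenance = path)
  validateMap(model)
}

`%|NA|%` <- function(a, b) if (length(a) != 1L || is.na(a)) b else a
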