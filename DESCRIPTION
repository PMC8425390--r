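Package: pdlint
Title: Composability Auditing and Harmonization of Process Description Pathway Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing the reusability and composability of SBGN
    process description (PD) pathway maps. Provides a typed in-memory graph
    model of PD maps (stateful protein and complex entity pools, processes,
    catalysis arcs), readers and writers for a CellDesigner-flavoured SBML
    subset and a native JSON interchange format, extraction of catalyzed
    phosphorylation events as kinase/target/site/map quadruplets (for free
    proteins and proteins inside complexes), a cross-map occurrence census of
    repeated phosphorylation patterns with detection of divergent
    representations, machine-checkable lints for the four recurrent
    composability barriers (generic versus specific entities, inconsistent
    state-variable universes, non-canonical phosphosite sets, and complex
    versus free-cascade variants), combinatorial expansion of complexes with
    generic components, and harmonization operations (state-variable
    propagation, generic-to-specific replacement, lint-guarded map merging).
    Ships deterministic synthetic reconstructions of RAS-RAF-MEK-ERK pathway
    fragments in the styles of the ACSN, PANTHER and Reactome databases, and
    a seeded random PD-map generator with embedded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    jsonlite,
    xml2,
    igraph,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'identity.R'
    'census.R'
    'lints.R'
    'expand.R'
    'fixtures.R'
    'harmonize.R'
    'map-io-native.R'
    'map-io-celldesigner.R'
    'pdlint-package.R'
    'pipeline.R'
    'random-map.R'
VignetteBuilder: knitr
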