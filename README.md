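# pdlint

Composability auditing of process-description pathway maps.

## The problem

Signalling pathways are curated as SBGN process-description (PD) maps —
diagrams whose nodes are stateful molecular entity pools (a protein
phosphorylated at given sites, a complex, a generic family placeholder) and
biochemical processes modulated by catalysis arcs. The same biochemical
fact is drawn again and again across maps and databases: RAF1 activating
MEK appears in ACSN, PANTHER and Reactome maps alike. In principle such
repeated fragments should be reusable building blocks. In practice they are
not, because curators represent the *same* event differently — with or
without explicit phosphosites, on a specific protein or a generic family
pool, as free entities or inside a complex — and those divergences silently
break any attempt to compose maps into larger networks.

`pdlint` makes those barriers visible and measurable. It

* reads and writes PD maps (CellDesigner-flavoured SBML and a canonical
  native JSON format),
* extracts every catalyzed phosphorylation as a **quadruplet**
  ⟨kinase, target, site, map⟩, both for free entity pools and for targets
  phosphorylated inside complexes,
* builds a cross-map **census** of the map-free triplets ⟨kinase, target,
  site⟩ with per-map occurrence counts, keeping the repeated patterns,
* detects repeated patterns that are **represented differently** across
  maps and says why (state signature, generic vs specific, site detail,
  free vs in-complex),
* **lints** four recurrent composability barriers: generic/specific
  conflicts, "once a variable, always a variable" violations,
  non-canonical activating phosphosite sets, and complex-versus-free
  variants of the same interaction,
* expands complexes containing generic components into all concrete
  **multiset combinations** (a MEK homo/heterodimer over MEK1 and MEK2
  yields `C(2+2-1, 2) = 3` dimers), and
* **harmonizes and merges** maps under lint guard: a merge with blocking
  findings fails loudly unless state-variable propagation and
  generic-to-specific replacement are applied first.

## Core model

A `MapModel` holds named `ProteinPool`, `ComplexPool` and `Process`
objects (S4, with validity checks for referential integrity). A pool's
state is a named character vector of **state variables**: residue tokens
like `S218` or flags like `activity`, with value `"P"` for phosphorylated,
`NA` for unset, or any other literal. Protein identity is normalized to a
key with precedence *UniProt accession > alias table > upper-cased label*,
so `MEK1` and `MAP2K1` meet at `Q02750` while a generic `MEK` pool keeps
its label key plus annotated member accessions.

Synthetic RAS–RAF–MEK–ERK fixtures in the style of the ACSN, PANTHER and
Reactome databases are first-class (`listPresets()`,
`buildFixture()`, `acsnPresetSet()`, …), along with a seeded random map
generator whose output embeds its own ground-truth event table
(`generateRandomMap()`), used to test the extractor against an oracle.

## Worked example

```r
library(pdlint)

maps   <- acsnPresetSet()                 # six ACSN-style maps
events <- do.call(rbind, lapply(maps, extractPhosphoEvents))
census <- groupPatterns(events)
filterRepeated(census)[, c("kinase", "target", "site", "nMaps", "total")]
#>   kinase target site nMaps total
#> 1    MEK    ERK          4     5
#> 2 P04049    MEK          3     3
#> 3    RAS P04049          3     3
```

The canonical RAF1→MEK activation (site unspecified: it is drawn with an
`activity` flag) recurs in exactly 3 maps. How differently is RAF1 itself
drawn? Ask the state-signature lint over the four distinct fragments:

```r
f <- lintStateSignature(maps[c("Adaptive Immunity", "Regulated Cell Death",
                               "Cell Survival", "EMT and Senescence")])
f[f$proteinKey == "P04049", "message"]
#> [1] "protein P04049 has 3 distinct state-variable signatures across 3 maps"
f[f$proteinKey == "P04049", ]$payload[[1]]$signatures
#> [1] ""
#> [2] "activity"
#> [3] "activity,S259,S289,S296,S301,S338,S621"
```

Stateless, a bare flag, or seven variables (six residue phosphosites plus
the flag) — three representations of one protein. Generic complexes expand
combinatorially:

```r
out <- expandGenericComplex(buildFixture("generic_mek_dimer"), "cx_mek_dimer")
vapply(out, function(x) paste(x$keys, collapse = " + "), character(1))
#> [1] "P36507 + P36507" "P36507 + Q02750" "Q02750 + Q02750"
```

And merging the canonical map with the detailed one is blocked until
harmonization unifies the RAF1 state universe:

```r
mergeMaps(list(buildFixture("acsn_canonical"),
               buildFixture("acsn_emt_raf1_detailed")))@success
#> [1] FALSE
rep <- mergeMaps(list(buildFixture("acsn_canonical"),
                      buildFixture("acsn_emt_raf1_detailed")),
                 autoHarmonize = TRUE, replaceGenerics = TRUE)
rep@success
#> [1] TRUE
sort(unique(unlist(lapply(
  Filter(function(p) p@proteinKey == "P04049", pools(rep@model)),
  stateSignature))))
#> [1] "activity" "S259"     "S289"     "S296"     "S301"     "S338"     "S621"
```

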