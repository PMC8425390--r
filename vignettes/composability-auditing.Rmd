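---
title: "Auditing the composability of process-description pathway maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the composability of process-description pathway maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdlint)
```

## Model and assumptions

`pdlint` treats a process-description (PD) map as a typed property graph:

* **Entity pools** (`ProteinPool`) carry a display label, a derived
  identity key, a compartment and a set of *state variables* — a named
  character vector mapping site tokens to values. A residue token matches
  `^[A-Z][1-9][0-9]*$` (e.g. `S218`); anything else (e.g. `activity`) is a
  flag. Value `"P"` means phosphorylated, `NA` unset; other literals (such
  as `"active"`) are legal and are never confused with phosphorylation.
* **Identity** is resolved with precedence *UniProt accession >
  alias-table hit > upper-cased label*. This is the pivotal modelling
  choice: all cross-map matching (census grouping, divergence, lints,
  merging) happens on identity keys, never on display labels, so `MEK1`
  and `MAP2K1` are one protein while a generic `MEK` pool keeps a distinct
  label key plus its annotated member accessions.
* **Complexes** (`ComplexPool`) are multisets of component pool
  references; their composition signature is order-independent.
* **Processes** carry reactants, products and typed modulators; only
  modulators of class `catalysis` make a state transition a candidate
  phosphorylation event (callers may opt in to `stimulation`).

An extracted event is the quadruplet ⟨kinase, target, site, map⟩. A site is
recorded only when a *residue* variable gains value `"P"` between a
reactant and a product pool of the same protein; a flag turning `"P"`
yields the empty site token (site unspecified). Two matching modes mirror
how curators draw phosphorylation: on free pools, and inside complexes —
the latter by multiset-cancelling identical components of the reactant and
product complexes and pairing the remainders by protein key, which also
handles homodimers where both copies change.

## Lints and their severities

* `STATE_SIGNATURE` — "once a variable, always a variable". Within a map,
  two pools of one protein with different site sets are an **error** (the
  map is internally inconsistent and unmergeable). Across maps, differing
  per-map universes are a **warning**, with the distinct signatures in the
  payload.
* `GENERIC_SPECIFIC` — a protein appearing both as a generic-pool member
  and as a specific pool is a **warning**; generics without annotated
  members get an `UNANNOTATED_GENERIC` **info** note.
* `CANONICAL_SITES` — phosphosite sets are compared against a
  user-configurable reference of canonical activating sites (defaults:
  MEK1 S218/S222, MEK2 S222/S226, ERK1 T202/Y204, ERK2 T185/Y187) and
  classified as superset, disjoint or other. The reference is data, not
  hard-coded behaviour.
* `COMPLEX_VARIANT` — the same proteins drawn as a complex in one map but
  composed differently, or interacting as free pools, in another.

Every finding cites at least one pool id and one map name.

## Divergence grouping

Repeated-pattern divergence does **not** group by literal (kinase, target)
strings: a generic `RAF` pool, a specific `RAF1` pool and a `RAS–RAF`
complex catalyst would then never meet. Instead, each event's kinase and
target resolve to identity-key *sets* (a generic contributes its members, a
complex the union over components), and events whose kinase sets *and*
target sets both intersect are linked; connected components of that
relation form the groups. A group with at least two events whose per-map
representation tuples (mode, generic status, target signature, site set)
differ is divergent. Consequently divergence is computed from the full
event table: restricting to a pre-filtered census would drop exactly the
cross-naming-style repeats the analysis exists to find (a census can still
be supplied to narrow the scope).

## Generator scope and what passing tests do not show

`generateRandomMap()` builds maps with per-protein fixed site universes
(so generated maps are within-map consistent by construction), plants free
and in-complex phosphorylation processes, and adds background noise —
associations and uncatalyzed transitions whose gained sites carry the
non-phospho value `"x"`. The planted processes are returned as a ground
truth table, and the extraction oracle requires exact agreement over 100
seeds. This demonstrates correctness of the extractor *on the generator's
vocabulary only*: real curated maps contain entity classes (genes, RNAs,
small molecules), reversible reactions, and layout-dependent conventions
the generator never emits; the CellDesigner reader skips such species with
warnings rather than modelling them. The fixture presets are likewise
stylized fragments — they reproduce the published counts by construction
of the scenario, not by measurement of the source databases.

## Numerical and serialization choices

* Expansion counts use the multiset-combination closed form
  `choose(k + m - 1, m)`; the test suite checks it against brute-force
  enumeration of all `k^m` assignments for `k, m ≤ 5`.
* The native JSON format is canonical: fixed key order, entities sorted by
  id, state variables sorted by site, so write∘read is byte-stable and
  structural equality is string equality (`nativeMapString()`).
  Provenance is runtime metadata and is not serialized.
* All tabular outputs are ordered deterministically
  (triplet-lexicographic census, sorted findings); the pipeline writes
  artifacts atomically (temp file + rename).
* RNG discipline: the generator saves and restores the caller's
  `.Random.seed`; everything else is deterministic.

## Design decisions on open questions

* **Merge harmonization order**: generics are replaced by their members
  *before* state-variable propagation; member pools inherit the generic's
  state and only after replacement share identity keys with specific pools
  elsewhere, so the union universe actually unifies them. The reverse
  order leaves within-map signature conflicts in the merged model.
* **Flag naming in fixtures**: the canonical fragment's RAF1 activity flag
  uses the same token (`activity`) as the detailed fragment, so the
  harmonized union is seven variables — one scenario choice, stated here
  rather than hidden.
* **Uniform substitution**: replacing a generic clones each touching
  process once per member with the member substituted uniformly;
  replacing several generics in sequence yields the cartesian fan-out.
* **Repeat threshold**: the census drops patterns with total occurrence
  below 2 (`filterRepeated`), configurable per call.

## Limitations

* Phosphorylation only; other modification types (ubiquitination,
  acetylation) would need their own value vocabulary.
* Dephosphorylation (site loss) is deliberately not an event.
* The CellDesigner dialect covered is the subset this package writes
  (proteins, complexes, modification residues, reaction types); layout,
  genes/RNAs and kinetic laws are out of scope.
* Complex-variant matching is exact on protein sets by default; subset
  matching (`allowSubset`) trades precision for recall.
* Divergence grouping is quadratic in the number of events per run —
  fine for map-scale inputs, not for database-scale corpora.
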