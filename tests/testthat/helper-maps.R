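# Tiny hand-built maps used across the unit tests. Kept deliberately
# minimal so the expected events/findings can be verified by eye.

# One kinase (XKIN) catalyzing XSUB unphosphorylated -> phosphorylated at S10.
tinyPhosphoMap <- function(mapName = "tiny", site = "S10") {
  MapModel(mapName, pools = list(
    ProteinPool("kin", label = "XKIN"),
    ProteinPool("sub_i", label = "XSUB",
                state = stateVariables(site)),
    ProteinPool("sub_a", label = "XSUB",
                state = stateVariables(site, "P"))),
    processes = list(
      Process("p1", reactants = "sub_i", products = "sub_a",
              modulators = c(kin = "catalysis"))))
}

# Same phosphorylation, but happening to XSUB inside an XKIN-XSUB complex.
tinyComplexMap <- function(mapName = "tinycx", site = "S10") {
  MapModel(mapName, pools = list(
    ProteinPool("kin", label = "XKIN"),
    ProteinPool("other", label = "XKIN"),
    ProteinPool("sub_i", label = "XSUB",
                state = stateVariables(site)),
    ProteinPool("sub_a", label = "XSUB",
                state = stateVariables(site, "P"))),
    complexes = list(
      ComplexPool("cx_i", c("other", "sub_i")),
      ComplexPool("cx_a", c("other", "sub_a"))),
    processes = list(
      Process("p1", reactants = "cx_i", products = "cx_a",
              modulators = c(kin = "catalysis"))))
}

# A within-map "once a variable, always a variable" violation: two XSUB
# pools with different site sets.
tinyInconsistentMap <- function(mapName = "broken") {
  MapModel(mapName, pools = list(
    ProteinPool("sub_1", label = "XSUB", state = stateVariables("S10")),
    ProteinPool("sub_2", label = "XSUB",
                state = stateVariables(c("S10", "T20")))))
}

# Generic pool over two members, with a specific pool of one member.
tinyGenericMap <- function(mapName = "gen") {
  MapModel(mapName, pools = list(
    ProteinPool("fam", label = "XFAM", isGeneric = TRUE,
                members = c("XA", "XB")),
    ProteinPool("xa", label = "XA")))
}

expect_same_model <- function(a, b) {
  expect_identical(nativeMapString(a), nativeMapString(b))
}
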