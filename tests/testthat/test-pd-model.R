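test_that("stateVariables builds sorted named vectors and validates tokens", {
  sv <- stateVariables(c("S222", "S218"), c("P", NA))
  expect_identical(names(sv), c("S218", "S222"))
  expect_identical(unname(sv), c(NA_character_, "P"))
  expect_identical(stateVariables(), stats::setNames(character(), character()))
  # flags (non-residue tokens) are legal site names, duplicates are not
  expect_silent(stateVariables("activity", "active"))
  expect_error(stateVariables(c("S10", "S10")))
  expect_error(stateVariables(""))
})

test_that("isResidueSite matches residue tokens only", {
  expect_true(all(isResidueSite(c("S218", "T185", "Y187", "K5"))))
  expect_false(any(isResidueSite(c("activity", "s218", "S0", "S01", "",
                                   "S218b"))))
})

test_that("protein identity precedence: accession > alias > label", {
  expect_identical(normalizeProteinIdentity("MEK1", "Q02750"), "Q02750")
  expect_identical(normalizeProteinIdentity("anything", c("Z9", "A1")), "A1")
  expect_identical(normalizeProteinIdentity("MAPK1"), "P28482")
  expect_identical(normalizeProteinIdentity(" mek1 "), "Q02750")
  expect_identical(normalizeProteinIdentity("novelProtX"), "NOVELPROTX")
  # idempotent: a key normalizes to itself
  k <- normalizeProteinIdentity("MEK1")
  expect_identical(normalizeProteinIdentity(k), k)
})

test_that("ProteinPool derives its key and keeps generics label-keyed", {
  p <- ProteinPool("x", label = "MEK1")
  expect_identical(p@proteinKey, "Q02750")
  g <- ProteinPool("g", label = "MEK", isGeneric = TRUE,
                   members = c("Q02750", "P36507"))
  expect_identical(g@proteinKey, "MEK")
  expect_identical(stateSignature(ProteinPool("y", "X",
    state = stateVariables(c("T2", "S1")))), c("S1", "T2"))
})

test_that("MapModel validity enforces referential integrity", {
  m <- tinyPhosphoMap()
  expect_s4_class(validateMap(m), "MapModel")
  # process referencing an unknown pool
  expect_error(MapModel("bad", pools = list(ProteinPool("a", "XA")),
                        processes = list(Process("p", reactants = "a",
                                                 products = "nope"))),
               "nope")
  # complex referencing an unknown component
  expect_error(MapModel("bad", complexes = list(ComplexPool("c", "ghost"))),
               "ghost")
  # duplicate pool ids
  expect_error(MapModel("bad", pools = list(ProteinPool("a", "XA"),
                                            ProteinPool("a", "XB"))))
  # undeclared compartment is auto-declared by the constructor
  m2 <- MapModel("ok", pools = list(ProteinPool("a", "XA",
                                                compartment = "nucleus")))
  expect_true("nucleus" %in% compartments(m2))
})

test_that("accessors and show methods work", {
  m <- tinyPhosphoMap("shown")
  expect_identical(mapName(m), "shown")
  expect_length(pools(m), 3L)
  expect_length(processes(m), 1L)
  expect_identical(poolId(pools(m)$kin), "kin")
  expect_output(show(m), "shown")
  expect_output(show(pools(m)$kin), "XKIN")
  expect_s4_class(getPool(m, "kin"), "ProteinPool")
  expect_error(getPool(m, "missing"))
  expect_false(isComplexId(m, "kin"))
  expect_true(isComplexId(tinyComplexMap(), "cx_i"))
})

test_that("process modulator classes are restricted", {
  expect_error(Process("p", "a", "b", modulators = c(x = "frobnication")))
  expect_silent(Process("p", "a", "b", modulators = c(x = "stimulation")))
  expect_error(Process("p", kind = "not_a_kind"))
})
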