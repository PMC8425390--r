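test_that("within-map signature violations are errors citing the pools", {
  f <- lintStateSignature(list(tinyInconsistentMap()))
  expect_identical(nrow(f), 1L)
  expect_identical(f$severity, "error")
  expect_identical(f$ruleId, "STATE_SIGNATURE")
  expect_true(grepl("sub_1", f$pools) && grepl("sub_2", f$pools))
  expect_identical(f$maps, "broken")
})

test_that("cross-map signature differences are warnings with payload", {
  a <- tinyPhosphoMap("a")              # XSUB universe {S10}
  b <- tinyPhosphoMap("b", site = "T20")  # XSUB universe {T20}
  f <- lintStateSignature(list(a, b))
  w <- f[f$severity == "warning" & f$proteinKey == "XSUB", ]
  expect_identical(nrow(w), 1L)
  expect_identical(w$payload[[1]]$nSignatures, 2L)
  expect_setequal(w$payload[[1]]$signatures, c("S10", "T20"))
  expect_true(nzchar(w$pools) && nzchar(w$maps))
})

test_that("identical universes across maps are silent", {
  f <- lintStateSignature(list(tinyPhosphoMap("a"), tinyPhosphoMap("b")))
  expect_identical(nrow(f), 0L)
})

test_that("generic/specific conflicts are flagged per member protein", {
  f <- lintGenericSpecific(list(tinyGenericMap()))
  g <- f[f$ruleId == "GENERIC_SPECIFIC", ]
  expect_identical(g$proteinKey, "XA")  # XB never appears specific
  expect_identical(g$severity, "warning")
  expect_true(grepl("fam", g$pools) && grepl("xa", g$pools))
})

test_that("unannotated generics get an info note", {
  m <- MapModel("u", pools = list(
    ProteinPool("g", "XFAM", isGeneric = TRUE)))
  f <- lintGenericSpecific(list(m))
  expect_identical(f$ruleId, "UNANNOTATED_GENERIC")
  expect_identical(f$severity, "info")
})

test_that("canonical-site lint classifies deviations", {
  ref <- canonicalSiteReference()
  expect_setequal(ref$Q02750, c("S218", "S222"))
  mk <- function(id, sites) MapModel(id, pools = list(
    ProteinPool("p1", "MEK1", state = stateVariables(sites, "P"))))
  # equal -> silent
  expect_identical(nrow(lintCanonicalSites(list(mk("eq", c("S218", "S222"))))),
                   0L)
  # superset
  f <- lintCanonicalSites(list(mk("sup", c("S218", "S222", "T286"))))
  expect_identical(f$payload[[1]]$class, "superset")
  # disjoint
  f <- lintCanonicalSites(list(mk("dis", c("T286", "T292"))))
  expect_identical(f$payload[[1]]$class, "disjoint")
  # partial overlap
  f <- lintCanonicalSites(list(mk("oth", c("S218", "T286"))))
  expect_identical(f$payload[[1]]$class, "other")
  # unknown protein: one info note
  m <- MapModel("unk", pools = list(
    ProteinPool("x1", "XNEW", state = stateVariables("S1", "P")),
    ProteinPool("x2", "XNEW", state = stateVariables("S1", "P"))))
  f <- lintCanonicalSites(list(m))
  expect_identical(nrow(f), 1L)
  expect_identical(f$severity, "info")
})

test_that("canonical reference is user-configurable and validated", {
  ref <- canonicalSiteReference(list(XNEW = c("S1", "S2")))
  expect_setequal(ref$XNEW, c("S1", "S2"))
  expect_error(canonicalSiteReference(list(XNEW = "activity")), "residue")
})

test_that("the L1CAM-style preset triggers a superset finding", {
  f <- lintCanonicalSites(list(buildFixture("reactome_l1cam_mek1")))
  expect_true(any(vapply(f$payload, function(p)
    identical(p$class, "superset"), logical(1))))
})

test_that("complex variant lint: same proteins, different composition", {
  mkcx <- function(nm, withP) MapModel(nm, pools = list(
    ProteinPool("a", "XA"),
    ProteinPool("b", "XB", state = stateVariables("S1",
                                                  if (withP) "P" else NA))),
    complexes = list(ComplexPool("cx", c("a", "b"))))
  f <- lintComplexVariants(list(mkcx("m1", FALSE), mkcx("m2", TRUE)))
  expect_identical(f$ruleId, "COMPLEX_VARIANT")
  expect_true(grepl("m1", f$maps) && grepl("m2", f$maps))
})

test_that("complex variant lint: complex versus free-pool process", {
  cxMap <- MapModel("withcx", pools = list(
    ProteinPool("a", "XA"), ProteinPool("b", "XB")),
    complexes = list(ComplexPool("cx", c("a", "b"))))
  freeMap <- MapModel("free", pools = list(
    ProteinPool("a", "XA"),
    ProteinPool("b_i", "XB", state = stateVariables("S1")),
    ProteinPool("b_a", "XB", state = stateVariables("S1", "P"))),
    processes = list(Process("p", "b_i", "b_a", c(a = "catalysis"))))
  f <- lintComplexVariants(list(cxMap, freeMap))
  expect_identical(nrow(f), 1L)
  expect_true(grepl("free", f$maps))
  # one map alone can never produce this cross-map finding
  expect_identical(nrow(lintComplexVariants(list(cxMap))), 0L)
})

test_that("generic components match specific pools in variant detection", {
  cxMap <- MapModel("gcx", pools = list(
    ProteinPool("raf", "RAF", isGeneric = TRUE,
                members = c("P04049", "P15056")),
    ProteinPool("m", "MEK1")),
    complexes = list(ComplexPool("cx", c("raf", "m"))))
  freeMap <- MapModel("gfree", pools = list(
    ProteinPool("raf1", "RAF1"),
    ProteinPool("m_i", "MEK1", state = stateVariables("S218")),
    ProteinPool("m_a", "MEK1", state = stateVariables("S218", "P"))),
    processes = list(Process("p", "m_i", "m_a", c(raf1 = "catalysis"))))
  f <- lintComplexVariants(list(cxMap, freeMap))
  expect_identical(nrow(f), 1L)
})

test_that("every finding cites at least one pool and one map", {
  models <- lapply(listPresets(), buildFixture)
  f <- lintMaps(models)
  expect_gt(nrow(f), 0L)
  expect_true(all(nzchar(f$pools)))
  expect_true(all(nzchar(f$maps)))
  expect_true(all(f$severity %in% c("error", "warning", "info")))
})

test_that("lintMaps honours the rules subset", {
  models <- list(buildFixture("acsn_canonical"),
                 buildFixture("acsn_emt_raf1_detailed"))
  f <- lintMaps(models, rules = "STATE_SIGNATURE")
  expect_true(all(f$ruleId == "STATE_SIGNATURE"))
  f2 <- lintMaps(models, rules = character())
  expect_identical(nrow(f2), 0L)
})
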