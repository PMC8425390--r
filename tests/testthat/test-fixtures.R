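test_that("every preset builds into a valid map", {
  ids <- listPresets()
  expect_gte(length(ids), 10L)
  for (id in ids) {
    m <- buildFixture(id)
    expect_s4_class(m, "MapModel")
    expect_s4_class(validateMap(m), "MapModel")
  }
  expect_error(buildFixture("no_such_preset"), "no_such_preset")
})

test_that("preset sets carry their database-style map names", {
  acsn <- acsnPresetSet()
  expect_length(acsn, 6L)
  nms <- vapply(acsn, mapName, character(1))
  expect_setequal(nms, c("Adaptive Immunity", "Innate Immunity",
                         "Cancer-Associated Fibroblasts", "Regulated Cell Death",
                         "Cell Survival", "EMT and Senescence"))
  # the canonical fragment is instantiated under three different map names
  expect_length(pantherPresetSet(), 3L)
  expect_length(reactomePresetSet(), 3L)
})

test_that("buildFixture map-name override works", {
  expect_identical(mapName(buildFixture("acsn_canonical", "Custom")),
                   "Custom")
})

test_that("clean presets have no within-map error findings", {
  for (id in setdiff(listPresets(), "reactome_l1cam_mek1")) {
    f <- lintMaps(list(buildFixture(id)))
    expect_identical(sum(f$severity == "error"), 0L, label = id)
  }
})

test_that("the deliberately inconsistent preset yields a within-map error", {
  f <- lintStateSignature(list(buildFixture("reactome_l1cam_mek1")))
  expect_true(any(f$severity == "error" & f$proteinKey == "Q02750"))
})

test_that("the random map generator is deterministic per seed", {
  a <- generateRandomMap(randomMapSpec(seed = 42))
  b <- generateRandomMap(randomMapSpec(seed = 42))
  expect_same_model(a$model, b$model)
  expect_identical(a$truth, b$truth)
  c <- generateRandomMap(randomMapSpec(seed = 43))
  expect_false(identical(nativeMapString(a$model), nativeMapString(c$model)))
})

test_that("the generator restores the caller's RNG state", {
  set.seed(7); before <- .Random.seed
  invisible(generateRandomMap(randomMapSpec(seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("infeasible generator settings are rejected up front", {
  expect_error(randomMapSpec(seed = 1, pInComplex = 0.5, nComplexes = 0),
               "infeasible")
  expect_error(randomMapSpec(seed = 1, nProteins = 0))
})

test_that("generated maps are valid and within-map consistent", {
  for (s in 1:5) {
    g <- generateRandomMap(randomMapSpec(seed = s))
    expect_s4_class(validateMap(g$model), "MapModel")
    f <- lintStateSignature(list(g$model))
    expect_identical(sum(f$severity == "error"), 0L)
  }
})
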