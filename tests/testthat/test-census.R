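test_that("free-mode extraction finds a hand-verifiable quadruplet", {
  ev <- extractPhosphoEvents(tinyPhosphoMap("m1"))
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kinase, "XKIN")
  expect_identical(ev$target, "XSUB")
  expect_identical(ev$site, "S10")
  expect_identical(ev$map, "m1")
  expect_identical(ev$mode, "free")
})

test_that("in-complex extraction pairs changed components", {
  ev <- extractPhosphoEvents(tinyComplexMap("m2"))
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$mode, "in_complex")
  expect_identical(ev$target, "XSUB")
  expect_identical(ev$site, "S10")
})

test_that("uncatalyzed transitions and non-P values yield no events", {
  m <- MapModel("quiet", pools = list(
    ProteinPool("a_i", "XA", state = stateVariables("S1")),
    ProteinPool("a_x", "XA", state = stateVariables("S1", "x")),
    ProteinPool("b_i", "XB", state = stateVariables("S2")),
    ProteinPool("b_p", "XB", state = stateVariables("S2", "P"))),
    processes = list(
      Process("p1", "a_i", "a_x", c(b_i = "catalysis")),  # value "x", not P
      Process("p2", "b_i", "b_p")))                       # no catalyst
  expect_identical(nrow(extractPhosphoEvents(m)), 0L)
})

test_that("a flag turning P records the event with unspecified site", {
  ev <- extractPhosphoEvents(buildFixture("acsn_canonical"))
  expect_true(all(ev$site == ""))
  expect_identical(nrow(ev), 3L)
})

test_that("stimulation modulators count only when asked", {
  m <- MapModel("stim", pools = list(
    ProteinPool("k", "XK"),
    ProteinPool("s_i", "XS", state = stateVariables("S1")),
    ProteinPool("s_a", "XS", state = stateVariables("S1", "P"))),
    processes = list(Process("p", "s_i", "s_a", c(k = "stimulation"))))
  expect_identical(nrow(extractPhosphoEvents(m)), 0L)
  ev <- extractPhosphoEvents(m, modulationClasses = c("catalysis",
                                                      "stimulation"))
  expect_identical(nrow(ev), 1L)
})

test_that("expandGenerics adds member-level rows and keeps label rows", {
  m <- buildFixture("acsn_canonical")
  ev <- extractPhosphoEvents(m, expandGenerics = TRUE)
  lab <- ev[!ev$expanded, ]
  exp <- ev[ev$expanded, ]
  expect_identical(nrow(lab), 3L)
  # RAF1 -> {MEK1, MEK2}; MEK -> {ERK1, ERK2} cartesian = 4
  expect_identical(nrow(exp), 6L)
  expect_true(all(c("Q02750", "P36507") %in%
                  exp$target[exp$kinase == "P04049"]))
  # expanded rows never enter the census
  expect_identical(sum(groupPatterns(ev)$total),
                   sum(groupPatterns(lab)$total))
})

test_that("census counts distinct processes per map and orders rows", {
  maps <- list(tinyPhosphoMap("a"), tinyPhosphoMap("b"), tinyComplexMap("c"))
  ev <- do.call(rbind, lapply(maps, extractPhosphoEvents))
  cen <- groupPatterns(ev)
  expect_s3_class(cen, "PatternCensus")
  row <- cen[cen$kinase == "XKIN" & cen$site == "S10", ]
  expect_identical(row$nMaps, 3L)
  expect_identical(row$total, 3L)
  expect_identical(row$perMap[[1]], c(a = 1L, b = 1L, c = 1L))
  expect_false(is.unsorted(paste(cen$kinase, cen$target, cen$site)))
})

test_that("filterRepeated drops singletons by default", {
  maps <- list(tinyPhosphoMap("a"), tinyPhosphoMap("b"),
               tinyPhosphoMap("c", site = "T99"))
  cen <- groupPatterns(do.call(rbind, lapply(maps, extractPhosphoEvents)))
  rep2 <- filterRepeated(cen)
  expect_identical(nrow(rep2), 1L)
  expect_identical(rep2$site, "S10")
  expect_identical(nrow(filterRepeated(cen, minTotal = 1L)), 2L)
  expect_identical(nrow(filterRepeated(cen, minTotal = 99L)), 0L)
})

test_that("census is invariant under pool/process id renaming", {
  m <- buildFixture("acsn_emt_raf1_detailed")
  p <- withr::local_tempfile(fileext = ".json")
  writeNativeMap(m, p)
  txt <- readLines(p)
  for (old in c("raf1", "mek1", "erk1", "p_")) {
    txt <- gsub(paste0('"', old), paste0('"zz_', old), txt)
  }
  m2 <- readNativeMap(p)  # unrenamed
  writeLines(txt, p)
  m3 <- readNativeMap(p)  # renamed ids, same content
  c2 <- groupPatterns(extractPhosphoEvents(m2))
  c3 <- groupPatterns(extractPhosphoEvents(m3))
  expect_identical(c2[, c("kinase", "target", "site", "nMaps", "total")],
                   c3[, c("kinase", "target", "site", "nMaps", "total")])
})

test_that("divergence groups by identity overlap across naming styles", {
  div <- findDivergentRepresentations(pantherPresetSet())
  rafMek <- div[grepl("P04049|RAF", div$kinases) & grepl("MEK", div$targets), ]
  expect_identical(nrow(rafMek), 1L)
  expect_true(rafMek$divergent)
  expect_true(grepl("generic_vs_specific|state_signature|mode",
                    rafMek$reasons))
})

test_that("identical representations are repeated but not divergent", {
  div <- findDivergentRepresentations(list(tinyPhosphoMap("a"),
                                           tinyPhosphoMap("b")))
  expect_identical(nrow(div), 1L)
  expect_true(div$repeated)
  expect_false(div$divergent)
  expect_identical(div$nVersions, 1L)
})

test_that("a census restriction narrows divergence analysis", {
  maps <- list(tinyPhosphoMap("a"), tinyPhosphoMap("b"))
  ev <- do.call(rbind, lapply(maps, extractPhosphoEvents))
  cen <- groupPatterns(ev)
  full <- findDivergentRepresentations(maps, census = cen)
  expect_identical(nrow(full), 1L)
  none <- findDivergentRepresentations(maps,
                                       census = cen[0, , drop = FALSE])
  expect_identical(nrow(none), 0L)
})

test_that("empty inputs yield empty, well-typed frames", {
  m <- MapModel("empty")
  ev <- extractPhosphoEvents(m)
  expect_identical(nrow(ev), 0L)
  cen <- groupPatterns(ev)
  expect_identical(nrow(cen), 0L)
  expect_identical(nrow(filterRepeated(cen)), 0L)
  expect_identical(nrow(findDivergentRepresentations(list(m))), 0L)
})
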