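# Brute-force oracle: enumerate all k^m member assignments for a complex of
# m generic copies over k members and collapse to distinct multisets.
bruteForceMultisets <- function(members, m) {
  grid <- do.call(expand.grid, c(rep(list(members), m),
                                 stringsAsFactors = FALSE))
  unique(apply(grid, 1L, function(r) paste(sort(r), collapse = "+")))
}

test_that("the MEK dimer expands to exactly 3 concrete dimers", {
  m <- buildFixture("generic_mek_dimer")
  out <- expandGenericComplex(m, "cx_mek_dimer")
  expect_length(out, 3L)
  expect_identical(length(out), as.integer(choose(2L + 2L - 1L, 2L)))
  keys <- vapply(out, function(x) paste(x$keys, collapse = "+"), character(1))
  expect_setequal(keys, c("P36507+P36507", "P36507+Q02750",
                          "Q02750+Q02750"))
  # member instances carry the generic's state
  gen <- Filter(function(p) p@isGeneric, pools(m))[[1]]
  expect_identical(stateSignature(out[[1]]$components[[1]]),
                   stateSignature(gen))
})

test_that("expansion counts match stars-and-bars and brute force, k,m <= 5", {
  for (k in 1:5) for (m in 1:5) {
    members <- sprintf("M%02d", seq_len(k))
    pools <- c(list(ProteinPool("g", "FAM", isGeneric = TRUE,
                                members = members)))
    model <- MapModel("sb", pools = pools,
                      complexes = list(ComplexPool("cx", rep("g", m))))
    out <- expandGenericComplex(model, "cx")
    expect_identical(length(out), as.integer(choose(k + m - 1L, m)),
                     label = sprintf("k=%d m=%d closed form", k, m))
    keys <- vapply(out, function(x) paste(x$keys, collapse = "+"),
                   character(1))
    expect_setequal(keys, bruteForceMultisets(members, m))
  }
})

test_that("mixed generic/specific complexes expand over generics only", {
  model <- MapModel("mix", pools = list(
    ProteinPool("g", "FAM", isGeneric = TRUE, members = c("A1", "B2")),
    ProteinPool("s", "XS")),
    complexes = list(ComplexPool("cx", c("g", "s"))))
  out <- expandGenericComplex(model, "cx")
  expect_length(out, 2L)
  expect_true(all(vapply(out, function(x) "XS" %in% x$keys, logical(1))))
})

test_that("inexpansible complexes raise errors", {
  m1 <- MapModel("e1", pools = list(ProteinPool("a", "XA"),
                                    ProteinPool("b", "XB")),
                 complexes = list(ComplexPool("cx", c("a", "b"))))
  expect_error(expandGenericComplex(m1, "cx"), "no generic")
  m2 <- MapModel("e2", pools = list(
    ProteinPool("g", "FAM", isGeneric = TRUE)),
    complexes = list(ComplexPool("cx", "g")))
  expect_error(expandGenericComplex(m2, "cx"), "members")
})

test_that("propagateStateVariables is idempotent, monotone and lossless", {
  m <- buildFixture("acsn_raf1_stateless")
  m1 <- propagateStateVariables(m, "P04049", c("S338", "activity"))
  raf <- Filter(function(p) p@proteinKey == "P04049", pools(m1))
  for (p in raf) expect_setequal(stateSignature(p), c("activity", "S338"))
  m2 <- propagateStateVariables(m1, "P04049", c("S338", "activity"))
  expect_same_model(m1, m2)
  # refusing to lose an existing site
  expect_error(propagateStateVariables(m1, "P04049", "S338"),
               "refusing")
  # existing values preserved
  can <- buildFixture("acsn_canonical")
  can2 <- propagateStateVariables(can, "P04049", c("activity", "S259"))
  expect_identical(pools(can2)$raf1_a@state[["activity"]], "P")
  expect_true(is.na(pools(can2)$raf1_a@state[["S259"]]))
})

test_that("replaceGenericWithSpecific fans processes out per member", {
  m <- buildFixture("acsn_canonical")
  r <- replaceGenericWithSpecific(m, "mek_i")
  expect_null(pools(r)$mek_i)
  keys <- vapply(pools(r), function(p) p@proteinKey, character(1))
  expect_true(all(c("Q02750", "P36507") %in% keys))
  # p_mek touched the generic: one clone per member
  expect_true(all(c("p_mek_Q02750", "p_mek_P36507") %in%
                  names(processes(r))))
  expect_false("p_mek" %in% names(processes(r)))
  expect_true(any(grepl("replace_generic mek_i",
                        attr(r, "transformLog"))))
  expect_error(replaceGenericWithSpecific(m, "raf1_i"), "not a generic")
  expect_error(replaceGenericWithSpecific(m, "mek_i",
                                          policy = "keep_single_member"),
               "exactly one member")
})

test_that("replacing generics preserves the member-level event set", {
  for (id in c("acsn_canonical", "panther_interleukin", "panther_fgf")) {
    m <- buildFixture(id)
    before <- extractPhosphoEvents(m, expandGenerics = TRUE)
    beforeKeys <- unique(paste(before$kinase, before$target, before$site))
    after <- extractPhosphoEvents(replaceAllGenerics(m))
    afterKeys <- unique(paste(after$kinase, after$target, after$site))
    # every triplet extracted after replacement was already implied by the
    # generic map, and every member-expanded triplet survives replacement
    expect_true(all(afterKeys %in% beforeKeys), label = id)
    expKeys <- unique(paste(before$kinase, before$target,
                            before$site)[before$expanded])
    expect_true(all(expKeys %in% afterKeys), label = id)
  }
})

test_that("merging conflicting maps is blocked without harmonization", {
  rep <- mergeMaps(list(buildFixture("acsn_canonical"),
                        buildFixture("acsn_emt_raf1_detailed")))
  expect_false(rep@success)
  expect_gt(nrow(rep@blocking), 0L)
  expect_true(any(rep@blocking$ruleId == "STATE_SIGNATURE"))
  expect_true(any(rep@blocking$ruleId == "GENERIC_SPECIFIC"))
  expect_output(show(rep), "FAILED")
})

test_that("auto-harmonized merge succeeds and unifies RAF1 state", {
  rep <- mergeMaps(list(buildFixture("acsn_canonical"),
                        buildFixture("acsn_emt_raf1_detailed")),
                   autoHarmonize = TRUE, replaceGenerics = TRUE)
  expect_true(rep@success)
  expect_s4_class(rep@model, "MapModel")
  expect_identical(sum(rep@postLint$severity == "error"), 0L)
  raf <- Filter(function(p) p@proteinKey == "P04049", pools(rep@model))
  uni <- unique(unlist(lapply(raf, stateSignature)))
  expect_setequal(uni, c("activity", "S259", "S289", "S296", "S301",
                         "S338", "S621"))
  expect_true(any(grepl("propagate P04049", rep@log)))
})

test_that("merging a map with itself reproduces its structure", {
  rep <- mergeMaps(list(buildFixture("acsn_canonical", "A"),
                        buildFixture("acsn_canonical", "B")))
  expect_true(rep@success)
  expect_length(pools(rep@model), length(pools(buildFixture("acsn_canonical"))))
  expect_length(processes(rep@model),
                length(processes(buildFixture("acsn_canonical"))))
})
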