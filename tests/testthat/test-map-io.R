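test_that("native JSON round trip is the identity on all presets", {
  for (id in listPresets()) {
    m <- buildFixture(id)
    p <- withr::local_tempfile(fileext = ".json")
    writeNativeMap(m, p)
    m2 <- readNativeMap(p)
    expect_same_model(m, m2)
  }
})

test_that("native writing is byte-stable across write/read/write", {
  m <- buildFixture("reactome_raf_map_kinase")
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  writeNativeMap(m, p1)
  writeNativeMap(readNativeMap(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("native reader reports structural problems with JSON paths", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines('{"pools": []}', p)
  expect_error(readNativeMap(p), "format_version")
  writeLines('{"format_version": "1.0", "map": {"pools": []}}', p)
  expect_error(readNativeMap(p), "map_name")
  writeLines(paste0('{"format_version": "1.0", "map": {"map_name": "x",',
                    ' "pools": [{"label": "A"}]}}'), p)
  expect_error(readNativeMap(p), "pools\\[0\\]")
  writeLines("this is not json", p)
  expect_error(readNativeMap(p))
})

test_that("CellDesigner round trip is the identity on all presets", {
  for (id in listPresets()) {
    m <- buildFixture(id)
    p <- withr::local_tempfile(fileext = ".xml")
    writeCellDesignerMap(m, p)
    m2 <- readCellDesignerMap(p, mapName = mapName(m))
    expect_same_model(m, m2)
  }
})

test_that("CellDesigner output is namespaced SBML with modification states", {
  m <- buildFixture("acsn_emt_raf1_detailed")
  p <- withr::local_tempfile(fileext = ".xml")
  writeCellDesignerMap(m, p)
  doc <- xml2::read_xml(p)
  ns <- xml2::xml_ns(doc)
  expect_true("http://www.sbml.org/2001/ns/celldesigner" %in% unlist(ns))
  txt <- readLines(p)
  expect_true(any(grepl('state="phosphorylated"', txt)))
  expect_true(any(grepl("celldesigner:listOfModificationResidues", txt)))
  expect_true(any(grepl('type="GENERIC"', txt, fixed = TRUE)) ||
              !any(vapply(pools(m), function(x) x@isGeneric, logical(1))))
})

test_that("CellDesigner reader fails on truncated XML", {
  m <- buildFixture("acsn_canonical")
  p <- withr::local_tempfile(fileext = ".xml")
  writeCellDesignerMap(m, p)
  txt <- readLines(p)
  writeLines(txt[seq_len(length(txt) - 5L)], p)
  expect_error(readCellDesignerMap(p))
})

test_that("unsupported species are skipped with a warning, not silently", {
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4"',
    ' xmlns:celldesigner="http://www.sbml.org/2001/ns/celldesigner">',
    '<model id="m" name="skipper">',
    '<listOfCompartments><compartment id="default"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="rna1" name="someRNA" compartment="default">',
    '<annotation><celldesigner:extension>',
    '<celldesigner:speciesIdentity>',
    '<celldesigner:class>RNA</celldesigner:class>',
    '</celldesigner:speciesIdentity>',
    '</celldesigner:extension></annotation></species>',
    '</listOfSpecies>',
    '<listOfReactions><reaction id="r1">',
    '<listOfReactants><speciesReference species="rna1"/></listOfReactants>',
    '</reaction></listOfReactions>',
    '</model></sbml>'), p)
  expect_warning(expect_warning(m <- readCellDesignerMap(p), "rna1"), "r1")
  expect_length(pools(m), 0L)
  expect_length(processes(m), 0L)
})

test_that("map name precedence: override > model name > file stem", {
  m <- buildFixture("acsn_canonical")
  p <- file.path(withr::local_tempdir(), "stemname.xml")
  writeCellDesignerMap(m, p)
  expect_identical(mapName(readCellDesignerMap(p, mapName = "forced")),
                   "forced")
  expect_identical(mapName(readCellDesignerMap(p)), mapName(m))
  txt <- sub(' name="Adaptive Immunity"', "", readLines(p))
  writeLines(txt, p)
  expect_identical(mapName(readCellDesignerMap(p)), "stemname")
})

test_that("readMapFile dispatches on extension", {
  m <- buildFixture("panther_fgf")
  d <- withr::local_tempdir()
  pj <- file.path(d, "m.json"); px <- file.path(d, "m.xml")
  writeNativeMap(m, pj); writeCellDesignerMap(m, px)
  expect_same_model(readMapFile(pj), m)
  expect_same_model(readMapFile(px, mapName = mapName(m)), m)
  expect_error(readMapFile(file.path(d, "m.csv")), "extension")
})
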