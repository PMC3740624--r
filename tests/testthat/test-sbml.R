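reg <- read_registry()

test_that("notes lines become typed annotations with validation warnings", {
  res <- extract_notes_annotations("FORMULA: C4H8N2O3\nCHARGE: 0")
  expect_length(res$annotations, 2)
  expect_ec_equal(res$annotations[[1]]$formula, c(C = 4L, H = 8L, N = 2L, O = 3L))
  expect_identical(res$annotations[[2]]$charge, 0L)

  res2 <- extract_notes_annotations("INCHI: InChI=1S/H2O/h1H2")
  expect_identical(res2$annotations[[1]]$kind, "structure")
  expect_identical(res2$annotations[[1]]$notation, "inchi")

  res3 <- extract_notes_annotations("KEGG: not-an-id")
  expect_length(res3$annotations, 0)
  expect_length(res3$warnings, 1)

  res4 <- extract_notes_annotations("KEGG: C00002\nfree text line",
                                    keep_unmatched = TRUE)
  expect_identical(res4$annotations[[1]]$kind, "crossref")
  expect_identical(res4$annotations[[2]]$value, "free text line")
})

test_that("a hand-written SBML file reads with species, CV terms and notes", {
  path <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    ' <model id="mini">',
    '  <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '  <listOfSpecies>',
    '   <species id="atp" metaid="meta_atp" name="ATP" compartment="c" constant="false"',
    '            hasOnlySubstanceUnits="false" boundaryCondition="false">',
    '    <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>FORMULA: C10H12N5O13P3</p></body></notes>',
    '    <annotation><rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '      xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">',
    '     <rdf:Description rdf:about="#meta_atp"><bqbiol:is><rdf:Bag>',
    '      <rdf:li rdf:resource="https://identifiers.org/chebi/CHEBI:15422"/>',
    '      <rdf:li rdf:resource="https://example.org/opaque"/>',
    '     </rdf:Bag></bqbiol:is></rdf:Description></rdf:RDF></annotation>',
    '   </species>',
    '   <species id="h2o" name="water" compartment="c" constant="false"',
    '            hasOnlySubstanceUnits="false" boundaryCondition="false"/>',
    '   <species id="amp" name="AMP" compartment="c" constant="false"',
    '            hasOnlySubstanceUnits="false" boundaryCondition="false"/>',
    '  </listOfSpecies>',
    '  <listOfReactions>',
    '   <reaction id="r1" reversible="false" fast="false">',
    '    <listOfReactants><speciesReference species="atp" stoichiometry="1" constant="true"/></listOfReactants>',
    '    <listOfProducts><speciesReference species="amp" stoichiometry="1" constant="true"/></listOfProducts>',
    '   </reaction>',
    '  </listOfReactions>',
    ' </model>',
    '</sbml>'), path)
  m <- read_sbml(path)
  expect_length(m$metabolites, 3)
  expect_length(m$reactions, 1)
  expect_false(m$reactions$r1$reversible)
  atp <- m$metabolites$atp
  xr <- annotations(atp, "crossref")
  expect_length(xr, 1)
  expect_identical(xr[[1]]$namespace, "chebi")
  expect_identical(xr[[1]]$identifier, "CHEBI:15422")
  # unresolvable URI preserved as note, never dropped
  notes <- vapply(annotations(atp, "note"), `[[`, character(1), "value")
  expect_true("https://example.org/opaque" %in% notes)
  expect_length(annotations(atp, "formula"), 1)
})

test_that("raw mode keeps notes verbatim for the transfer step", {
  m0 <- model("t")
  met <- metabolite("glygly", "glycylglycine", "c")
  met <- add_annotation(met, ann_formula("C4H8N2O3"))
  attr(met, "added") <- NULL
  m0 <- model_add_metabolite(m0, met)
  path <- tempfile(fileext = ".xml")
  write_sbml(m0, path)
  raw <- read_sbml(path, extract_notes = FALSE)
  anns <- annotations(raw$metabolites$glygly)
  expect_true(all(vapply(anns, `[[`, character(1), "kind") == "note"))
  expect_identical(anns[[1]]$value, "FORMULA: C4H8N2O3")
})

test_that("write-read round-trip preserves the model and its annotations", {
  m <- toy_atp_model()
  m <- model_annotate(m, "atp", ann_crossref("chebi", "CHEBI:30616"))
  m <- model_annotate(m, "atp", ann_crossref("kegg.compound", "C00002"))
  m <- model_annotate(m, "atp", ann_synonym("adenosine 5'-triphosphate"))
  m <- model_annotate(m, "h2o", ann_structure("inchi", "InChI=1S/H2O/h1H2"))
  m <- model_annotate(m, "h2o", ann_note("solvent"))
  m <- model_annotate(m, "R_atph", ann_crossref("kegg.reaction", "R00086"))
  attr(m, "added") <- NULL
  path <- tempfile(fileext = ".xml")
  write_sbml(m, path)
  m2 <- read_sbml(path)
  expect_true(metanno:::model_equal(m, m2))
  # two xrefs emit two CV-term URIs on one species
  doc <- xml2::read_xml(path)
  lis <- xml2::xml_find_all(doc, "//*[local-name()='species'][@id='atp']//*[local-name()='li']")
  expect_length(lis, 2)
  # InChI-only metabolite carries exactly one INCHI notes line
  txt <- xml2::xml_text(xml2::xml_find_all(
    doc, "//*[local-name()='species'][@id='h2o']//*[local-name()='p']"))
  expect_identical(sum(grepl("^INCHI:", txt)), 1L)
})

test_that("half-integer stoichiometry survives the SBML round trip exactly", {
  m <- model("t")
  for (id in c("o2", "h2o", "h2")) m <- model_add_metabolite(m, metabolite(id))
  m <- model_add_reaction(m, reaction("r", c(h2 = 1, o2 = 0.5), c(h2o = 1)))
  path <- tempfile(fileext = ".xml")
  write_sbml(m, path)
  p <- read_sbml(path)$reactions$r$participants
  expect_identical(p$num[p$metabolite == "o2"], 1)
  expect_identical(p$den[p$metabolite == "o2"], 2)
})

test_that("invalid inputs fail loudly", {
  bad <- tempfile(fileext = ".xml")
  writeLines("<sbml><model>", bad)
  expect_error(read_sbml(bad))
  dangling <- tempfile(fileext = ".xml")
  writeLines(c(
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="x"><listOfSpecies>',
    '<species id="a" compartment="c" constant="false" hasOnlySubstanceUnits="false" boundaryCondition="false"/>',
    '</listOfSpecies><listOfReactions><reaction id="r" reversible="false">',
    '<listOfReactants><speciesReference species="ghost" stoichiometry="1" constant="true"/></listOfReactants>',
    '</reaction></listOfReactions></model></sbml>'), dangling)
  expect_error(read_sbml(dangling), "unknown metabolites")
  # xref that cannot validate blocks the write, naming the entity
  m <- model("t")
  met <- metabolite("a")
  met$annotations <- list(ann_crossref("chebi", "broken"))
  m <- model_add_metabolite(m, met)
  expect_error(write_sbml(m, tempfile()), "a")
})
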