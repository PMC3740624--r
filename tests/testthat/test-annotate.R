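reg <- read_registry()

unstructured_met <- function(id, name, xrefs = list()) {
  met <- metabolite(id, name, "c")
  for (x in xrefs) met <- add_annotation(met, ann_crossref(x[1], x[2]))
  attr(met, "added") <- NULL
  met
}

test_that("xref lookup attaches the first indexed structure", {
  idx <- toy_index()
  m <- model("t")
  m <- model_add_metabolite(m, unstructured_met("atp", "adenosine triphosphate",
                                                list(c("chebi", "CHEBI:15422"))))
  res <- annotate_by_xref(m, idx)
  expect_length(res$decisions, 1)
  d <- res$decisions[[1]]
  expect_true(d$accepted)
  expect_identical(d$method, "xref_lookup")
  expect_true(metanno:::has_structure(res$model$metabolites$atp))
  # already-structured metabolites are skipped entirely
  res2 <- annotate_by_xref(res$model, idx)
  expect_length(res2$decisions, 0)
})

test_that("conflicting structures across cross references are rejected", {
  rows <- data.frame(
    identifier = c("CHEBI:10", "CHEBI:11"), name = c("foo", "foo2"),
    synonyms = "", formula = c("H2O", "CO2"), charge = 0L, inchi = "",
    smiles = c("O", "O=C=O"), stringsAsFactors = FALSE)
  idx <- toy_index(rows)
  m <- model("t")
  m <- model_add_metabolite(m, unstructured_met(
    "x", "mystery", list(c("chebi", "CHEBI:10"), c("chebi", "CHEBI:11"))))
  res <- annotate_by_xref(m, idx)
  d <- res$decisions[[1]]
  expect_false(d$accepted)
  expect_identical(d$rationale, "conflict")
  expect_false(metanno:::has_structure(res$model$metabolites$x))
})

test_that("silent name search attaches only unique exact hits", {
  idx <- toy_index()
  m <- model("t")
  m <- model_add_metabolite(m, unstructured_met("atp", "atp"))
  res <- annotate_by_name(m, idx, "silent")
  d <- res$decisions[[1]]
  expect_true(d$accepted)
  expect_identical(d$method, "name_exact")
  expect_identical(d$score, 1)
  expect_true(metanno:::has_structure(res$model$metabolites$atp))
  xr <- annotations(res$model$metabolites$atp, "crossref")
  expect_identical(xr[[1]]$identifier, "CHEBI:15422")
})

test_that("ambiguous exact hits are never silently attached", {
  rows <- data.frame(
    identifier = c("CHEBI:20", "CHEBI:21"), name = c("glucose", "Glucose"),
    synonyms = "", formula = "", charge = "", inchi = "",
    smiles = c("OCC1OC(O)C(O)C(O)C1O", "OC1OC(CO)C(O)C(O)C1O"),
    stringsAsFactors = FALSE)
  idx <- toy_index(rows)
  m <- model("t")
  m <- model_add_metabolite(m, unstructured_met("glc", "glucose"))
  res <- annotate_by_name(m, idx, "silent")
  d <- res$decisions[[1]]
  expect_false(d$accepted)
  expect_match(d$rationale, "ambiguous")
  expect_match(d$chosen, "CHEBI:20")
  expect_match(d$chosen, "CHEBI:21")
  expect_false(metanno:::has_structure(res$model$metabolites$glc))
})

test_that("suggest mode emits scored, unaccepted candidates only", {
  idx <- toy_index()
  m <- model("t")
  m <- model_add_metabolite(m, unstructured_met("glc", "glucose"))
  res <- annotate_by_name(m, idx, "suggest", threshold = 0.2)
  expect_gt(length(res$decisions), 0)
  for (d in res$decisions) {
    expect_identical(d$method, "name_ranked")
    expect_false(d$accepted)
    expect_false(is.na(d$score))
    expect_gte(d$score, 0.2)
  }
  expect_false(metanno:::has_structure(res$model$metabolites$glc))
  # reviewed decisions can then be applied, attaching xref + structure
  accepted <- res$decisions
  accepted[[1]]$accepted <- TRUE
  res2 <- apply_decisions(res$model, accepted, idx)
  expect_length(res2$decisions, 1)
  expect_true(metanno:::has_structure(res2$model$metabolites$glc))
})

test_that("notes transfer promotes typed annotations and logs decisions", {
  m <- model("t")
  met <- metabolite("a", "thing", "c")
  met <- add_annotation(met, ann_note("INCHI: InChI=1S/H2O/h1H2"))
  met <- add_annotation(met, ann_note("CHARGE: 0"))
  attr(met, "added") <- NULL
  m <- model_add_metabolite(m, met)
  res <- transfer_structures(m)
  expect_true(metanno:::has_structure(res$model$metabolites$a))
  expect_identical(metanno:::entity_charge(res$model$metabolites$a), 0L)
  expect_true(all(vapply(res$decisions, `[[`, logical(1), "accepted")))
  # second run adds nothing
  res2 <- transfer_structures(res$model)
  expect_length(res2$decisions, 0)
})

test_that("notes formula conflicting with a structure formula is rejected", {
  m <- model("t")
  met <- metabolite("a", "thing", "c")
  met <- add_annotation(met, ann_structure("inchi", "InChI=1S/H2O/h1H2"))
  met <- add_annotation(met, ann_note("FORMULA: CO2"))
  attr(met, "added") <- NULL
  m <- model_add_metabolite(m, met)
  res <- transfer_structures(m)
  expect_length(res$decisions, 1)
  expect_false(res$decisions[[1]]$accepted)
  expect_identical(res$decisions[[1]]$rationale, "conflict")
  expect_length(annotations(res$model$metabolites$a, "formula"), 0)
})

test_that("peptide names parse under both naming conventions", {
  tb <- residue_table()
  expect_identical(as.character(parse_peptide_name("Gly-Gly", tb)), c("gly", "gly"))
  expect_identical(as.character(parse_peptide_name("Ala-Gly-Ser", tb)),
                   c("ala", "gly", "ser"))
  expect_identical(as.character(parse_peptide_name("glycylglycine", tb)),
                   c("gly", "gly"))
  pep <- parse_peptide_name("L-alanyl-L-glutamate", tb)
  expect_identical(as.character(pep), c("ala", "glu"))
  expect_identical(attr(pep, "stereo"), c("l", "l"))
  expect_null(parse_peptide_name("glucosylglycine", tb))
  expect_null(parse_peptide_name("D-glucose", tb))
  expect_null(parse_peptide_name("glycylglycyl", tb))  # dangling combining name
})

test_that("greedy segmentation agrees with exhaustive segmentation", {
  tb <- residue_table()
  combining <- vapply(tb, `[[`, character(1), "combining")
  fulls <- unlist(unname(lapply(tb, function(r) {
    stats::setNames(rep(r$code, length(r$full_names)),
                    gsub("[- ]", "", r$full_names))
  })))
  # exhaustive left-to-right segmentation oracle (all splits, not greedy)
  all_segmentations <- function(s) {
    if (s %in% names(fulls)) return(list(fulls[[s]]))
    out <- list()
    for (code in names(combining)) {
      pre <- combining[[code]]
      if (startsWith(s, pre)) {
        for (tail in all_segmentations(substr(s, nchar(pre) + 1, nchar(s))))
          out[[length(out) + 1]] <- c(code, tail)
      }
    }
    out
  }
  set.seed(5)
  codes <- names(tb)
  for (i in 1:60) {
    n <- sample(2:3, 1)
    seqr <- codes[sample.int(length(codes), n, replace = TRUE)]
    name <- paste0(paste0(vapply(seqr[-n], function(cd) tb[[cd]]$combining,
                                 character(1)), collapse = ""),
                   tb[[seqr[n]]]$full_names[1])
    segs <- all_segmentations(gsub("[- ]", "", name))
    parsed <- parse_peptide_name(name, tb)
    expect_false(is.null(parsed), label = name)
    # the greedy parse is among the valid segmentations and unique here
    expect_length(segs, 1)
    expect_identical(as.character(parsed), as.character(segs[[1]]), label = name)
  }
})

test_that("assembled peptides obey the condensation formula law", {
  tb <- residue_table()
  water <- c(H = 2L, O = 1L)
  cases <- list(c("gly", "gly"), c("ala", "gly"), c("gly", "gly", "gly"),
                c("trp", "pro"), c("cys", "met", "his"))
  for (rs in cases) {
    s <- assemble_peptide(rs, tb)
    # oracle: independent per-element sum of free-residue formulas
    want <- oracle_balance(c(
      lapply(rs, function(cd) list(formula = format_formula(tb[[cd]]$formula),
                                   coeff = 1, side = "product")),
      list(list(formula = "H2O", coeff = length(rs) - 1, side = "reactant"))))
    expect_ec_equal(s$formula, want)
    expect_identical(s$charge, 0L)
  }
  expect_identical(format_formula(assemble_peptide(c("gly", "gly"), tb)$formula),
                   "C4H8N2O3")
  expect_identical(format_formula(assemble_peptide(c("ala", "gly"), tb)$formula),
                   "C5H10N2O3")
  expect_identical(format_formula(assemble_peptide(c("gly", "gly", "gly"), tb)$formula),
                   "C6H11N3O4")
  expect_error(assemble_peptide("gly", tb), "at least 2")
  expect_error(assemble_peptide(c("gly", "zzz"), tb), "unknown residue")
})

test_that("assembled SMILES agree with an independent cheminformatics toolkit", {
  # cross-check, not a substitute: the combinatorial formula is primary
  tb <- residue_table()
  set.seed(13)
  codes <- names(tb)
  cases <- c(lapply(1:8, function(i) codes[sample.int(20, 2, replace = TRUE)]),
             lapply(1:4, function(i) codes[sample.int(20, 3, replace = TRUE)]))
  smiles <- vapply(cases, function(rs) assemble_peptide(rs, tb)$smiles, character(1))
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "from rdkit.Chem.rdMolDescriptors import CalcMolFormula",
    "for line in sys.stdin:",
    "    m = Chem.MolFromSmiles(line.strip())",
    "    print(CalcMolFormula(m) if m else 'PARSE_FAIL')",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script)), input = smiles,
                 stdout = TRUE, stderr = FALSE)
  for (i in seq_along(cases)) {
    expect_ec_equal(parse_formula(out[i]),
                    assemble_peptide(cases[[i]], tb)$formula)
  }
})

test_that("peptide annotation and manual attachment fill empty slots only", {
  m <- model("t")
  m <- model_add_metabolite(m, unstructured_met("gg", "glycylglycine"))
  m <- model_add_metabolite(m, unstructured_met("other", "mystery"))
  res <- annotate_peptides(m)
  expect_length(res$decisions, 1)
  expect_identical(res$decisions[[1]]$metabolite_id, "gg")
  f <- metanno:::entity_formula(res$model$metabolites$gg)
  expect_identical(format_formula(f$formula), "C4H8N2O3")
  # second run: nothing left to do
  expect_length(annotate_peptides(res$model)$decisions, 0)

  p <- tempfile()
  writeLines("InChI=1S/H2O/h1H2", p)
  res2 <- attach_structure_file(res$model, "other", p)
  expect_true(res2$decisions[[1]]$accepted)
  res3 <- attach_structure_file(res2$model, "other", p)
  expect_false(res3$decisions[[1]]$accepted)  # never overwrite
})

test_that("the full pipeline is idempotent and decisions log round-trips", {
  idx <- toy_index()
  m <- model("t")
  m <- model_add_metabolite(m, unstructured_met("atp", "atp"))
  m <- model_add_metabolite(m, unstructured_met("gg", "glycylglycine"))
  res <- annotate_model(m, idx)
  expect_gt(length(res$decisions), 0)
  res2 <- annotate_model(res$model, idx)
  expect_length(res2$decisions, 0)
  p <- tempfile()
  write_decision_log(res$decisions, p)
  back <- read_decision_log(p)
  expect_length(back, length(res$decisions))
  expect_identical(back[[1]]$metabolite_id, res$decisions[[1]]$metabolite_id)
  expect_identical(back[[1]]$accepted, res$decisions[[1]]$accepted)
})
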