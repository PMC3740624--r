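test_that("ATP hydrolysis balances exactly against the integer-sum oracle", {
  m <- toy_atp_model()
  eb <- element_balance("R_atph", m)
  expect_length(eb, 0)
  want <- oracle_balance(list(
    list(formula = "C10H12N5O13P3", coeff = 1, side = "reactant"),
    list(formula = "H2O", coeff = 1, side = "reactant"),
    list(formula = "C10H12N5O10P2", coeff = 1, side = "product"),
    list(formula = "HO4P", coeff = 1, side = "product"),
    list(formula = "H", coeff = 1, side = "product")))
  expect_length(want, 0)
  expect_identical(charge_balance("R_atph", m), 0)
  expect_identical(balance_report("R_atph", m)$status, "balanced")
})

test_that("omitting the proton reports {H: -1} and charge -1", {
  m <- toy_atp_model(include_h = FALSE)
  eb <- element_balance("R_atph", m)
  want <- oracle_balance(list(
    list(formula = "C10H12N5O13P3", coeff = 1, side = "reactant"),
    list(formula = "H2O", coeff = 1, side = "reactant"),
    list(formula = "C10H12N5O10P2", coeff = 1, side = "product"),
    list(formula = "HO4P", coeff = 1, side = "product")))
  expect_identical(sorted_ec(eb), structure(as.numeric(want), names = names(want)))
  expect_identical(unname(eb["H"]), -1)
  expect_identical(charge_balance("R_atph", m), -1)
  expect_identical(balance_report("R_atph", m)$status, "imbalanced")
})

test_that("coefficients scale balances exactly", {
  m <- model("t")
  met <- add_annotation(metabolite("A", "A"), ann_formula("H2O"))
  met <- add_annotation(met, ann_charge(0L))
  attr(met, "added") <- NULL
  m <- model_add_metabolite(m, met)
  m <- model_add_reaction(m, reaction("r", c(A = 2), c(A = 1)))
  eb <- element_balance("r", m)
  expect_identical(sorted_ec(eb), c(H = -2, O = -1))
  # scaling all coefficients scales every imbalance entry
  m2 <- model_add_reaction(m, reaction("r2", c(A = 1), c(A = 0.5)))
  expect_identical(sorted_ec(element_balance("r2", m2)), c(H = -1, O = -0.5))
})

test_that("reversal negates element and charge deltas", {
  m <- toy_atp_model(include_h = FALSE)
  rev_rxn <- reaction("R_rev", c(adp = 1, pi = 1), c(atp = 1, h2o = 1))
  m <- model_add_reaction(m, rev_rxn)
  fwd <- element_balance("R_atph", m)
  bwd <- element_balance("R_rev", m)
  expect_identical(sorted_ec(fwd), -sorted_ec(bwd))
  expect_identical(charge_balance("R_atph", m), -charge_balance("R_rev", m))
})

test_that("missing formulas and generic elements make status undetermined", {
  m <- model("t")
  m <- model_add_metabolite(m, metabolite("A", "A"))  # no formula, no charge
  met <- add_annotation(metabolite("B", "B"), ann_formula("H2O"))
  met <- add_annotation(met, ann_charge(0L))
  attr(met, "added") <- NULL
  m <- model_add_metabolite(m, met)
  m <- model_add_reaction(m, reaction("r", c(A = 1), c(B = 1)))
  expect_null(element_balance("r", m))
  expect_true(is.na(charge_balance("r", m)))
  br <- balance_report("r", m)
  expect_identical(br$status, "undetermined")
  expect_identical(br$missing, "A")

  mg <- model("t2")
  metg <- add_annotation(metabolite("P", "polymer"), ann_formula("C2H4R"))
  metg <- add_annotation(metg, ann_charge(0L))
  attr(metg, "added") <- NULL
  mg <- model_add_metabolite(mg, metg)
  mg <- model_add_reaction(mg, reaction("r", c(P = 1), c(P = 1)))
  expect_identical(balance_report("r", mg)$status, "undetermined")
})

test_that("one-sided reactions are exempt as exchanges", {
  m <- toy_atp_model()
  m <- model_add_reaction(m, structure(
    list(id = "EX_atp", name = "EX_atp",
         participants = metanno:::new_participants("atp", 1, 1, "product"),
         reversible = TRUE, annotations = list()),
    class = "mm_reaction"))
  expect_identical(balance_report("EX_atp", m)$status, "exchange")
})

test_that("a condensation reaction built from the residue table conserves mass", {
  tb <- residue_table()
  m <- model("t")
  for (spec in list(c("g1", "gly", "C2H5NO2"), c("a1", "ala", "C3H7NO2"))) {
    met <- add_annotation(metabolite(spec[1], spec[2]),
                          ann_formula(format_formula(tb[[spec[2]]]$formula)))
    met <- add_annotation(met, ann_charge(0L))
    attr(met, "added") <- NULL
    m <- model_add_metabolite(m, met)
  }
  pep <- assemble_peptide(c("ala", "gly"), tb)
  metp <- add_annotation(metabolite("pep", "L-alanylglycine"),
                         ann_formula(pep$formula))
  metp <- add_annotation(metp, ann_charge(0L))
  w <- add_annotation(metabolite("h2o", "H2O"), ann_formula("H2O"))
  w <- add_annotation(w, ann_charge(0L))
  attr(metp, "added") <- attr(w, "added") <- NULL
  m <- model_add_metabolite(m, metp)
  m <- model_add_metabolite(m, w)
  m <- model_add_reaction(m, reaction("cond", c(a1 = 1, g1 = 1),
                                      c(pep = 1, h2o = 1)))
  expect_identical(balance_report("cond", m)$status, "balanced")
})

test_that("model report aggregates defects deterministically", {
  m <- toy_atp_model()
  rep <- model_report(m)
  expect_identical(rep$imbalanced, character(0))
  expect_identical(unname(rep$counts["reactions"]), 1L)
  expect_identical(rep$missing_structure, sort(names(m$metabolites)))
  # delete one formula: that reaction becomes undetermined, metabolite listed
  m2 <- m
  m2$metabolites$pi$annotations <-
    Filter(function(a) a$kind != "formula", m2$metabolites$pi$annotations)
  rep2 <- model_report(m2)
  expect_identical(rep2$undetermined, "R_atph")
  expect_true("pi" %in% rep2$balance$R_atph$missing)
  # duplicate normalized names form one group of two
  m3 <- model_add_metabolite(m, metabolite("atp2", "atp", "c"))
  rep3 <- model_report(m3)
  expect_identical(rep3$duplicate_names, list(c("atp", "atp2")))
})
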