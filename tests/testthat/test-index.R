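reg <- read_registry()

test_that("name normalization folds case, Greek letters and punctuation", {
  expect_identical(normalize_name("D-Glucose 6-phosphate"), "d glucose 6 phosphate")
  expect_identical(normalize_name("α-D-glucose"), "alpha d glucose")
  expect_identical(normalize_name("N-Acetyl,L-(glutamate)"), "n acetyl l glutamate")
  for (x in c("ATP", "β-alanine", "  spaced   out  ", "già-ncörmalized"))
    expect_identical(normalize_name(normalize_name(x)), normalize_name(x))
})

test_that("index building skips pattern-invalid identifiers with warnings", {
  idx <- toy_index()
  expect_length(idx$records, 4)
  expect_length(attr(idx, "warnings"), 0)

  bad_rows <- data.frame(
    identifier = c("CHEBI:1", "XYZ", "CHEBI:2"),
    name = c("one", "two", "three"), synonyms = "", formula = "",
    charge = "", inchi = "", smiles = "", stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".tsv")
  utils::write.table(bad_rows, p, sep = "\t", quote = FALSE, row.names = FALSE)
  idx2 <- build_index(read_resource_table(p, "chebi", reg), reg)
  expect_length(idx2$records, 2)
  expect_length(attr(idx2, "warnings"), 1)
  expect_error(read_resource_table(p, "not-a-namespace", reg), "unknown namespace")
})

test_that("multi-table indexes keep namespaces distinct", {
  t1 <- data.frame(identifier = "CHEBI:15422", name = "ATP", synonyms = "",
                   formula = "", charge = "", inchi = "", smiles = "",
                   stringsAsFactors = FALSE)
  t2 <- data.frame(identifier = "C00002", name = "ATP", synonyms = "",
                   formula = "", charge = "", inchi = "", smiles = "",
                   stringsAsFactors = FALSE)
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  utils::write.table(t1, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(t2, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  idx <- build_index(list(read_resource_table(p1, "chebi", reg),
                          read_resource_table(p2, "kegg.compound", reg)), reg)
  expect_length(idx$records, 2)
  expect_identical(lookup_xref(idx, list(namespace = "chebi",
                                         identifier = "CHEBI:15422"))$namespace,
                   "chebi")
  expect_identical(lookup_xref(idx, list(namespace = "kegg.compound",
                                         identifier = "C00002"))$namespace,
                   "kegg.compound")
})

test_that("exact search matches normalized primary names and synonyms", {
  idx <- toy_index()
  expect_identical(search_exact(idx, "atp")[[1]]$identifier, "CHEBI:15422")
  expect_identical(search_exact(idx, "AQUA")[[1]]$primary_name, "water")
  expect_length(search_exact(idx, "unobtainium"), 0)
})

test_that("ranked search scores by trigram Jaccard with exact matches first", {
  rows <- data.frame(
    identifier = c("CHEBI:1", "CHEBI:2"), name = c("glucose", "fructose"),
    synonyms = "", formula = "", charge = "", inchi = "", smiles = "",
    stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".tsv")
  utils::write.table(rows, p, sep = "\t", quote = FALSE, row.names = FALSE)
  idx <- build_index(read_resource_table(p, "chebi", reg), reg)
  res <- search_ranked(idx, "glucose", 10)
  expect_identical(res[[1]]$record$primary_name, "glucose")
  expect_identical(res[[1]]$score, 1)
  # second hit frozen against the explicit trigram enumeration
  expect_equal(res[[2]]$score, oracle_trigram_score("glucose", "fructose"))
  expect_length(search_ranked(idx, "glucose", 1), 1)
  # zero-score records are excluded
  expect_length(search_ranked(idx, "zzzzzz", 10), 0)
})

test_that("ranked scores match the brute-force oracle and are symmetric", {
  set.seed(99)
  vocab <- c("glucose", "fructose", "galactose", "lactate", "pyruvate",
             "citrate", "alanine", "glutamine", "glycine", "serine")
  rand_name <- function() paste(sample(vocab, sample(1:2, 1)), collapse = " ")
  for (i in 1:40) {
    a <- rand_name(); b <- rand_name()
    rows <- data.frame(identifier = "CHEBI:7", name = b, synonyms = "",
                       formula = "", charge = "", inchi = "", smiles = "",
                       stringsAsFactors = FALSE)
    p <- tempfile(fileext = ".tsv")
    utils::write.table(rows, p, sep = "\t", quote = FALSE, row.names = FALSE)
    idx <- build_index(read_resource_table(p, "chebi", reg), reg)
    res <- search_ranked(idx, a, 1)
    want <- oracle_trigram_score(normalize_name(a), normalize_name(b))
    got <- if (length(res) == 0) 0 else res[[1]]$score
    expect_equal(got, want, label = paste(a, "vs", b))
    # symmetry: swap query and record
    rows$name <- a
    utils::write.table(rows, p, sep = "\t", quote = FALSE, row.names = FALSE)
    idx2 <- build_index(read_resource_table(p, "chebi", reg), reg)
    res2 <- search_ranked(idx2, b, 1)
    got2 <- if (length(res2) == 0) 0 else res2[[1]]$score
    expect_equal(got2, got)
  }
})

test_that("exact hits are a subset of ranked hits at score 1.0", {
  idx <- toy_index()
  for (q in c("ATP", "aqua", "glycine")) {
    exact_ids <- vapply(search_exact(idx, q), `[[`, character(1), "identifier")
    ranked <- search_ranked(idx, q, 100)
    ones <- vapply(Filter(function(r) r$score == 1, ranked),
                   function(r) r$record$identifier, character(1))
    expect_true(all(exact_ids %in% ones))
  }
})

test_that("xref lookup is strict about canonical identifiers", {
  idx <- toy_index()
  expect_identical(lookup_xref(idx, list(namespace = "chebi",
                                         identifier = "CHEBI:15422"))$primary_name,
                   "ATP")
  expect_null(lookup_xref(idx, list(namespace = "chebi", identifier = "CHEBI:99999")))
  # bare digits are not canonicalized here: that is xref()'s job
  expect_null(lookup_xref(idx, list(namespace = "chebi", identifier = "15422")))
})

test_that("index persists deterministically and reloads equivalently", {
  idx <- toy_index()
  p1 <- tempfile(); p2 <- tempfile()
  write_index(idx, p1)
  write_index(idx, p2)
  expect_identical(readLines(p1), readLines(p2))
  idx2 <- read_index(p1)
  expect_identical(length(idx2$records), length(idx$records))
  expect_identical(search_exact(idx2, "ATP")[[1]]$identifier, "CHEBI:15422")
  p3 <- tempfile()
  write_index(idx2, p3)
  expect_identical(readLines(p1), readLines(p3))
  notidx <- tempfile()
  writeLines('{"format":"other"}', notidx)
  expect_error(read_index(notidx), "not a metanno index")
})
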