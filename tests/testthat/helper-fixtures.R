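# Shared in-code fixtures: a small annotated model, a toy resource index,
# and independent oracles kept deliberately separate from the package
# implementation they check.

# ATP hydrolysis with standard anion formulas and charges
toy_atp_model <- function(include_h = TRUE) {
  specs <- list(
    atp = list("ATP", "C10H12N5O13P3", -4L),
    h2o = list("H2O", "H2O", 0L),
    adp = list("ADP", "C10H12N5O10P2", -3L),
    pi  = list("phosphate", "HO4P", -2L),
    h   = list("H+", "H", 1L))
  if (!include_h) specs$h <- NULL
  m <- model("toy")
  for (id in names(specs)) {
    s <- specs[[id]]
    met <- metabolite(id, s[[1]], "c")
    met <- add_annotation(met, ann_formula(s[[2]]))
    met <- add_annotation(met, ann_charge(s[[3]]))
    attr(met, "added") <- NULL
    m <- model_add_metabolite(m, met)
  }
  products <- if (include_h) c(adp = 1, pi = 1, h = 1) else c(adp = 1, pi = 1)
  model_add_reaction(m, reaction("R_atph", c(atp = 1, h2o = 1), products))
}

# small resource index built from an in-code table
toy_index <- function(rows = NULL, registry = read_registry()) {
  if (is.null(rows)) rows <- data.frame(
    identifier = c("CHEBI:15422", "CHEBI:15377", "CHEBI:4167", "CHEBI:15428"),
    name = c("ATP", "water", "D-Glucose", "glycine"),
    synonyms = c("adenosine triphosphate", "H2O|aqua", "grape sugar", ""),
    formula = c("C10H16N5O13P3", "H2O", "C6H12O6", "C2H5NO2"),
    charge = c(0L, 0L, 0L, 0L),
    inchi = c("", "InChI=1S/H2O/h1H2", "", "InChI=1S/C2H5NO2/c3-1-2(4)5/h1,3H2,(H,4,5)"),
    smiles = c("OCC1OC(n2cnc3c(N)ncnc32)C(O)C1OP(O)(=O)OP(O)(=O)OP(O)(O)=O",
               "O", "OCC1OC(O)C(O)C(O)C1O", "NCC(O)=O"),
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  build_index(read_resource_table(path, "chebi", registry), registry)
}

# --- independent oracles -------------------------------------------------

# character-walk formula oracle: regex token scan, independent of
# parse_formula's implementation
oracle_formula <- function(text) {
  toks <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  stopifnot(sum(nchar(toks)) == nchar(text))
  syms <- sub("[0-9]*$", "", toks)
  cnts <- as.integer(ifelse(grepl("[0-9]", toks), sub("^[A-Za-z]+", "", toks), "1"))
  out <- tapply(cnts, syms, sum)
  out <- out[out != 0]
  v <- as.integer(out); names(v) <- names(out)
  v[order(names(v))]
}

# per-element integer-sum balance oracle over explicit participant lists:
# products minus reactants of coefficient * element count
oracle_balance <- function(parts) {
  # parts: list of list(formula = "...", coeff = n, side = "reactant"/"product")
  tot <- c()
  for (p in parts) {
    f <- oracle_formula(p$formula)
    sgn <- if (p$side == "product") 1 else -1
    for (e in names(f)) tot[e] <- (if (e %in% names(tot)) tot[[e]] else 0) +
        sgn * p$coeff * f[[e]]
  }
  tot <- tot[tot != 0]
  tot[order(names(tot))]
}

# brute-force trigram Jaccard, enumerated independently
oracle_trigram_score <- function(a, b) {
  grams <- function(s) {
    if (nchar(s) < 3) return(character(0))
    unique(sapply(1:(nchar(s) - 2), function(i) substr(s, i, i + 2)))
  }
  if (identical(a, b)) return(1)
  ta <- grams(a); tb <- grams(b)
  if (!length(ta) || !length(tb)) return(0)
  length(intersect(ta, tb)) / length(union(ta, tb))
}

sorted_ec <- function(x) x[order(names(x))]

expect_ec_equal <- function(actual, expected) {
  a <- sorted_ec(actual); b <- sorted_ec(expected)
  storage.mode(a) <- storage.mode(b) <- "double"  # exact small integers
  expect_identical(a, b)
}
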