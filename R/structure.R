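# Chemical structures as line notations (InChI and/or SMILES) with derived
# element counts and formal charge.

#' Create a chemical structure
#'
#' A structure holds an InChI and/or a SMILES plus, optionally, explicit
#' element counts and a formal charge. At least one of the three content
#' fields must be present. When an InChI is given and no formula, the
#' formula layer of the InChI is parsed to derive the element counts; a
#' supplied formula that contradicts the InChI formula layer is an error.
#' SMILES strings are carried opaquely (no SMILES interpreter is embedded).
#'
#' @param inchi InChI string or `NULL`.
#' @param smiles SMILES string or `NULL`.
#' @param formula Named integer vector of element counts, a formula string,
#'   or `NULL`.
#' @param charge Integer formal charge or `NULL` (unknown).
#' @return Object of class `mm_structure`.
#' @examples
#' chemical_structure(inchi = "InChI=1S/H2O/h1H2")
#' @export
chemical_structure <- function(inchi = NULL, smiles = NULL, formula = NULL,
                               charge = NULL) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (is.null(inchi) && is.null(smiles) && is.null(formula))
    stop("structure needs at least one of inchi, smiles, formula", call. = FALSE)
  if (!is.null(inchi)) {
    derived <- inchi_formula(inchi)
    if (!is.null(derived)) {
      if (is.null(formula)) {
        formula <- derived
      } else if (!ec_equal(formula, derived)) {
        stop(sprintf("formula %s disagrees with InChI formula layer %s",
                     format_formula(formula), format_formula(derived)),
             call. = FALSE)
      }
    }
    derived_q <- inchi_charge(inchi)
    if (is.null(charge) && !is.null(derived_q)) charge <- derived_q
  }
  structure(
    list(inchi = inchi, smiles = smiles,
         formula = if (is.null(formula)) NULL else ec_clean(formula),
         charge = if (is.null(charge)) NULL else as.integer(charge)),
    class = "mm_structure")
}

# Element counts from the formula layer of a standard InChI
# ("InChI=1S/C2H5NO2/c...") . Component formulas separated by "." with
# optional leading multipliers are summed. NULL when the layer is absent
# or unparseable.
inchi_formula <- function(inchi) {
  if (!grepl("^InChI=", inchi)) return(NULL)
  layers <- strsplit(inchi, "/", fixed = TRUE)[[1]]
  if (length(layers) < 2) return(NULL)
  flayer <- layers[2]
  total <- ec_clean(c())
  for (comp in strsplit(flayer, ".", fixed = TRUE)[[1]]) {
    mult <- 1L
    m <- regmatches(comp, regexec("^([0-9]+)(.*)$", comp))[[1]]
    if (length(m) == 3 && nzchar(m[2])) {
      mult <- as.integer(m[2]); comp <- m[3]
    }
    counts <- tryCatch(parse_formula(comp), error = function(e) NULL)
    if (is.null(counts)) return(NULL)
    total <- formula_combine(total, counts, mult, +1L)
  }
  total
}

# Net charge from the /q layer of an InChI; NULL when absent (neutral
# standard InChIs omit the layer, so absence means 0 only by convention --
# we return 0 for parseable standard InChIs without a /q layer).
inchi_charge <- function(inchi) {
  if (!grepl("^InChI=", inchi)) return(NULL)
  layers <- strsplit(inchi, "/", fixed = TRUE)[[1]]
  q <- grep("^q[+-]?[0-9]", layers, value = TRUE)
  if (length(q) == 0) return(0L)
  as.integer(sub("^q", "", q[1]))
}

# Best-available element counts for a structure: explicit formula first,
# else InChI-derived (already folded into $formula at construction).
structure_formula <- function(s) s$formula

#' @export
print.mm_structure <- function(x, ...) {
  cat("<chemical structure>\n")
  if (!is.null(x$inchi)) cat("  InChI:  ", x$inchi, "\n", sep = "")
  if (!is.null(x$smiles)) cat("  SMILES: ", x$smiles, "\n", sep = "")
  if (!is.null(x$formula)) cat("  formula:", format_formula(x$formula), "\n")
  if (!is.null(x$charge)) cat("  charge: ", x$charge, "\n", sep = "")
  invisible(x)
}
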