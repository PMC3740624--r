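# Element-count algebra over molecular formulas.
#
# An element count is a named integer vector, e.g. c(C = 10, H = 12, N = 5).
# Zero entries are never stored; names match ^[A-Z][a-z]?$. Symbols are not
# validated against the periodic table so generic/polymer placeholders such
# as "R" or "X" parse — draft reconstructions contain them, and the
# consistency checker flags (rather than rejects) reactions using them.

#' Parse a molecular formula into element counts
#'
#' Walks a Hill-style formula string (`"C10H12N5O13P3"`, `"FeS"`, `"H2O"`)
#' and returns the exact element multiset as a named integer vector. Any
#' symbol of the form capital letter plus optional lowercase letter is
#' accepted; counts default to 1. Repeated symbols are summed.
#'
#' @param text Formula string, e.g. `"C6H12O6"`.
#' @return Named integer vector of element counts, zero entries removed.
#' @examples
#' parse_formula("H2O")
#' parse_formula("C10H12N5O13P3")
#' @seealso [format_formula()], [formula_combine()]
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(trimws(text)))
    stop("formula must be a non-empty string", call. = FALSE)
  text <- trimws(text)
  counts <- c()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (!grepl("^[A-Z]$", ch))
      stop(sprintf("malformed formula '%s': unexpected character '%s' at position %d",
                   text, ch, i), call. = FALSE)
    sym <- ch
    i <- i + 1L
    if (i <= n && grepl("^[a-z]$", substr(text, i, i))) {
      sym <- paste0(sym, substr(text, i, i))
      i <- i + 1L
    }
    num <- ""
    while (i <= n && grepl("^[0-9]$", substr(text, i, i))) {
      num <- paste0(num, substr(text, i, i))
      i <- i + 1L
    }
    k <- if (nzchar(num)) as.integer(num) else 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + k
  }
  ec_clean(counts)
}

# drop zeros, coerce to integer, keep stable
ec_clean <- function(counts) {
  if (is.null(counts) || length(counts) == 0) return(stats::setNames(integer(0), character(0)))
  counts <- counts[counts != 0]
  storage.mode(counts) <- "integer"
  counts
}

ec_hill_order <- function(symbols) {
  has_c <- "C" %in% symbols
  if (has_c) {
    rest <- setdiff(symbols, c("C", "H"))
    c("C", intersect("H", symbols), sort(rest))
  } else {
    sort(symbols)
  }
}

#' Serialize element counts in Hill order
#'
#' Canonical serialization: carbon first, then hydrogen, then remaining
#' elements alphabetically (plain alphabetical when no carbon). Counts of 1
#' are omitted. The output re-parses to the same element multiset, so it is
#' stable under `parse_formula(format_formula(x))`.
#'
#' @param counts Named integer vector as returned by [parse_formula()].
#' @return Formula string, `""` for an empty count vector.
#' @examples
#' format_formula(parse_formula("O1H2"))  # "H2O"
#' @export
format_formula <- function(counts) {
  counts <- ec_clean(counts)
  if (length(counts) == 0) return("")
  ord <- ec_hill_order(names(counts))
  paste0(vapply(ord, function(s) {
    k <- counts[[s]]
    if (k == 1L) s else paste0(s, k)
  }, character(1)), collapse = "")
}

#' Combine element counts: a + sign * b_scale * b
#'
#' Per-element integer arithmetic used by peptide assembly (residue sums
#' minus condensation water) and by balance bookkeeping. Subtraction that
#' would drive any element negative is an error naming the element.
#'
#' @param a,b Named integer vectors of element counts.
#' @param b_scale Positive integer multiplier applied to `b`.
#' @param sign `+1` to add, `-1` to subtract.
#' @return Named integer vector; zero entries removed.
#' @examples
#' gly <- parse_formula("C2H5NO2")
#' water <- parse_formula("H2O")
#' formula_combine(formula_combine(gly, gly, 1, +1), water, 1, -1)  # Gly-Gly
#' @export
formula_combine <- function(a, b, b_scale = 1L, sign = 1L) {
  stopifnot(sign %in% c(-1L, 1L), b_scale >= 1)
  a <- ec_clean(a); b <- ec_clean(b)
  out <- a
  for (sym in names(b)) {
    cur <- if (sym %in% names(out)) out[[sym]] else 0L
    val <- cur + sign * b_scale * b[[sym]]
    if (val < 0)
      stop(sprintf("element count for '%s' would become negative (%d)", sym, val),
           call. = FALSE)
    out[sym] <- val
  }
  ec_clean(out)
}

# TRUE if counts contain a generic placeholder element (R, X, Z, *):
# conservation cannot be asserted over unknowns.
ec_has_generic <- function(counts) {
  any(names(counts) %in% c("R", "X", "Z"))
}

ec_equal <- function(a, b) {
  a <- ec_clean(a); b <- ec_clean(b)
  if (length(a) != length(b)) return(FALSE)
  if (!setequal(names(a), names(b))) return(FALSE)
  all(a[names(b)] == b)
}
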