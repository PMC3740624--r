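# Exact rational arithmetic for stoichiometric coefficients.
#
# Coefficients are kept as reduced integer num/den pairs so half-integer
# stoichiometry (0.5 lipid, 0.5 O2, ...) balances exactly instead of to
# within floating-point error. Stored as two plain numeric columns
# (num, den) on participant tables; all helpers below operate on those.

rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

# reduce to lowest terms, den > 0
rat_reduce <- function(num, den) {
  stopifnot(all(den != 0))
  s <- ifelse(den < 0, -1, 1)
  num <- num * s; den <- den * s
  g <- mapply(rat_gcd, num, den)
  g[g == 0] <- 1
  list(num = num / g, den = den / g)
}

# Parse a coefficient token: integer ("2"), decimal ("0.5", parsed exactly
# as k/10^d), or fraction ("1/3"). Returns list(num, den) or NULL.
rat_parse <- function(text) {
  text <- trimws(text)
  if (grepl("^[0-9]+$", text)) {
    return(list(num = as.numeric(text), den = 1))
  }
  if (grepl("^[0-9]+\\.[0-9]+$", text)) {
    parts <- strsplit(text, ".", fixed = TRUE)[[1]]
    d <- nchar(parts[2])
    num <- as.numeric(parts[1]) * 10^d + as.numeric(parts[2])
    return(rat_reduce(num, 10^d))
  }
  if (grepl("^[0-9]+/[0-9]+$", text)) {
    parts <- as.numeric(strsplit(text, "/", fixed = TRUE)[[1]])
    if (parts[2] == 0) return(NULL)
    return(rat_reduce(parts[1], parts[2]))
  }
  NULL
}

rat_add <- function(n1, d1, n2, d2) rat_reduce(n1 * d2 + n2 * d1, d1 * d2)
rat_mul <- function(n1, d1, n2, d2) rat_reduce(n1 * n2, d1 * d2)

# TRUE when den is of form 2^a * 5^b, i.e. the value has a finite decimal
# expansion and can be printed (and re-parsed) exactly.
rat_is_decimal <- function(den) {
  while (den %% 2 == 0) den <- den / 2
  while (den %% 5 == 0) den <- den / 5
  den == 1
}

# Canonical coefficient text: exact decimal for decimal-representable
# rationals ("0.5"), "num/den" otherwise ("1/3").
rat_format <- function(num, den) {
  if (den == 1) return(format(num, scientific = FALSE))
  if (rat_is_decimal(den)) {
    d <- 0; dd <- den
    while (dd %% 2 == 0) { dd <- dd / 2; d <- d + 1 }
    e2 <- d
    d <- 0
    while (dd %% 5 == 0) { dd <- dd / 5; d <- d + 1 }
    digits <- max(e2, d)
    scaled <- num * 10^digits / den
    int <- scaled %/% 10^digits
    frac <- scaled %% 10^digits
    fs <- formatC(frac, width = digits, flag = "0", format = "d")
    return(paste0(format(int, scientific = FALSE), ".", fs))
  }
  paste0(format(num, scientific = FALSE), "/", format(den, scientific = FALSE))
}
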