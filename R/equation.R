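# Human-readable reaction equations.
#
# Grammar: one arrow per equation ("->"/"=>" irreversible L-to-R, "<-"/"<="
# irreversible R-to-L, "<->"/"<=>" reversible); participants separated by
# " + " (plus with surrounding spaces, so names containing internal plus
# signs or hyphens survive); optional leading coefficient as a bare number
# ("2", "0.5", "1/2") or parenthesized "(2)"; optional trailing compartment
# suffix "[c]". Metabolite names may contain spaces ("D-glucose
# 6-phosphate"). One-sided exchange reactions must name the empty side
# explicitly with "∅" or "nothing".

ARROWS <- list("<=>" = "rev", "<->" = "rev",
               "=>" = "fwd", "->" = "fwd",
               "<=" = "back", "<-" = "back")

#' Parse a reaction equation
#'
#' Splits the equation at its single arrow, parses each side into
#' participants with exact rational coefficients (absent coefficient = 1)
#' and separates the compartment suffix from the name. Right-to-left arrows
#' (`"<-"`, `"<="`) are normalized by swapping sides so the stored direction
#' is always left-to-right. Duplicate names on one side are merged by
#' summing coefficients, with a warning.
#'
#' @param text Equation text, e.g. `"2 A + 3 B <=> C"` or
#'   `"atp[c] + h2o[c] -> adp[c] + pi[c] + h[c]"`.
#' @return Object of class `mm_equation`: a list with `participants`
#'   (data.frame `name`, `compartment`, `num`, `den`, `side`) and
#'   `reversible`.
#' @examples
#' eq <- parse_equation("2 A + 3 B <=> C")
#' eq$participants
#' @export
parse_equation <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty equation", call. = FALSE)

  # locate the arrow: longest tokens first so "<=>" is not read as "<="
  found <- NULL
  for (tok in names(ARROWS)) {
    if (grepl(tok, text, fixed = TRUE)) { found <- tok; break }
  }
  if (is.null(found))
    stop("no reaction arrow (->, =>, <-, <=, <->, <=>) in: ", text, call. = FALSE)
  pieces <- strsplit(text, found, fixed = TRUE)[[1]]
  if (length(pieces) != 2)
    stop("equation must contain exactly one arrow: ", text, call. = FALSE)
  # any second arrow of another kind is also an error
  remainder <- paste(pieces, collapse = " ")
  for (tok in names(ARROWS))
    if (grepl(tok, remainder, fixed = TRUE))
      stop("equation must contain exactly one arrow: ", text, call. = FALSE)

  kind <- ARROWS[[found]]
  lhs <- pieces[1]; rhs <- pieces[2]
  if (kind == "back") { tmp <- lhs; lhs <- rhs; rhs <- tmp }  # store as L->R

  parse_side <- function(side_text, side) {
    side_text <- trimws(side_text)
    if (!nzchar(side_text))
      stop("empty reaction side; use '∅' or 'nothing' for exchange reactions",
           call. = FALSE)
    if (side_text %in% c("∅", "nothing", "Nothing", "NOTHING"))
      return(NULL)
    terms <- strsplit(side_text, " + ", fixed = TRUE)[[1]]
    rows <- lapply(terms, function(term) {
      term <- trimws(term)
      if (!nzchar(term)) stop("empty participant in equation", call. = FALSE)
      num <- 1; den <- 1
      m <- regmatches(term, regexec("^\\(([0-9./]+)\\)\\s+(.*)$", term))[[1]]
      if (length(m) == 3) {
        r <- rat_parse(m[2])
        if (is.null(r)) stop("bad coefficient '", m[2], "' in: ", term, call. = FALSE)
        num <- r$num; den <- r$den; term <- trimws(m[3])
      } else {
        m <- regmatches(term, regexec("^([0-9]+(?:\\.[0-9]+)?(?:/[0-9]+)?)\\s+(.*)$",
                                      term, perl = TRUE))[[1]]
        if (length(m) == 3) {
          r <- rat_parse(m[2])
          if (is.null(r)) stop("bad coefficient '", m[2], "' in: ", term, call. = FALSE)
          num <- r$num; den <- r$den; term <- trimws(m[3])
        }
      }
      if (num == 0) stop("coefficient must be positive in: ", term, call. = FALSE)
      comp <- NA_character_
      cm <- regmatches(term, regexec("^(.*)\\[([A-Za-z0-9_]+)\\]$", term))[[1]]
      if (length(cm) == 3) { term <- trimws(cm[2]); comp <- cm[3] }
      if (!nzchar(term)) stop("missing metabolite name in equation term", call. = FALSE)
      data.frame(name = term, compartment = comp, num = num, den = den,
                 side = side, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }

  parts <- rbind(parse_side(lhs, "reactant"), parse_side(rhs, "product"))
  if (is.null(parts) || nrow(parts) == 0)
    stop("equation has no participants", call. = FALSE)

  # merge duplicates within a side (spreadsheet equations repeat species)
  key <- paste(parts$side, parts$name, ifelse(is.na(parts$compartment), "", parts$compartment))
  if (anyDuplicated(key)) {
    warning("duplicate participants merged by summing coefficients", call. = FALSE)
    merged <- list()
    for (i in seq_len(nrow(parts))) {
      k <- key[i]
      if (is.null(merged[[k]])) {
        merged[[k]] <- parts[i, ]
      } else {
        r <- rat_add(merged[[k]]$num, merged[[k]]$den, parts$num[i], parts$den[i])
        merged[[k]]$num <- r$num; merged[[k]]$den <- r$den
      }
    }
    parts <- do.call(rbind, merged)
    rownames(parts) <- NULL
  }

  structure(list(participants = parts, reversible = kind == "rev"),
            class = "mm_equation")
}

#' Format a reaction equation
#'
#' Canonical serialization: coefficients omitted when 1 (exact decimals for
#' dyadic rationals, `num/den` otherwise), participants in stored order,
#' compartment suffix printed whenever known, `"<=>"` for reversible and
#' `"->"` for irreversible reactions. `parse_equation(format_equation(x))`
#' is a fixpoint of [parse_equation()].
#'
#' @param x An `mm_equation` (from [parse_equation()]) or an `mm_reaction`.
#' @param model Required when `x` is a reaction: the `mm_model` supplying
#'   participant names and compartments.
#' @param ... Unused.
#' @return Equation text.
#' @examples
#' format_equation(parse_equation("2 A + B -> C"))
#' @export
format_equation <- function(x, ...) UseMethod("format_equation")

fmt_participants <- function(parts, reversible) {
  fmt_side <- function(df) {
    if (is.null(df) || nrow(df) == 0) return("∅")
    paste(vapply(seq_len(nrow(df)), function(i) {
      cf <- if (df$num[i] == 1 && df$den[i] == 1) "" else
        paste0(rat_format(df$num[i], df$den[i]), " ")
      comp <- if (is.na(df$compartment[i])) "" else paste0("[", df$compartment[i], "]")
      paste0(cf, df$name[i], comp)
    }, character(1)), collapse = " + ")
  }
  arrow <- if (reversible) "<=>" else "->"
  paste(fmt_side(parts[parts$side == "reactant", , drop = FALSE]), arrow,
        fmt_side(parts[parts$side == "product", , drop = FALSE]))
}

#' @rdname format_equation
#' @export
format_equation.mm_equation <- function(x, ...) {
  fmt_participants(x$participants, x$reversible)
}

#' @rdname format_equation
#' @export
format_equation.mm_reaction <- function(x, model, ...) {
  missing_ids <- setdiff(x$participants$metabolite, names(model$metabolites))
  if (length(missing_ids) > 0)
    stop("reaction references unknown metabolites: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  parts <- x$participants
  parts$name <- vapply(parts$metabolite, function(id) model$metabolites[[id]]$name,
                       character(1))
  parts$compartment <- vapply(parts$metabolite,
                              function(id) model$metabolites[[id]]$compartment,
                              character(1))
  fmt_participants(parts, x$reversible)
}
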