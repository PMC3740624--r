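# In-memory metabolic model: metabolites, reactions, compartments.
#
# Containers are plain named lists under an "mm_model" S3 class; updates are
# functional (helpers return the modified model). Referential integrity --
# every reaction participant resolves to a model metabolite, every
# metabolite compartment is declared -- is enforced at insertion.

#' Create a metabolite
#'
#' @param id Model-unique token.
#' @param name Display name (free text; may contain spaces/hyphens).
#' @param compartment Compartment token, e.g. `"c"`.
#' @return Object of class `mm_metabolite`.
#' @examples
#' metabolite("atp", "ATP", "c")
#' @export
metabolite <- function(id, name = id, compartment = "c") {
  stopifnot(is.character(id), nzchar(id))
  structure(list(id = id, name = name, compartment = compartment,
                 annotations = list()),
            class = "mm_metabolite")
}

# participants: data.frame(metabolite, num, den, side) with side in
# c("reactant","product") and num/den a reduced positive rational.
new_participants <- function(metabolite = character(0), num = numeric(0),
                             den = numeric(0), side = character(0)) {
  stopifnot(all(side %in% c("reactant", "product")), all(num > 0), all(den > 0))
  data.frame(metabolite = metabolite, num = num, den = den, side = side,
             stringsAsFactors = FALSE)
}

#' Create a reaction
#'
#' Participants reference metabolite ids with exact rational coefficients.
#' Coefficients may be given as a numeric vector (decimals are converted to
#' exact rationals) or as a `num`/`den` pair.
#'
#' @param id Reaction token.
#' @param reactants,products Named numeric vectors: names are metabolite
#'   ids, values are coefficients (e.g. `c(atp = 1, h2o = 1)`).
#' @param reversible Logical.
#' @param name Display name.
#' @return Object of class `mm_reaction`.
#' @examples
#' reaction("R1", c(atp = 1, h2o = 1), c(adp = 1, pi = 1, h = 1))
#' @export
reaction <- function(id, reactants, products, reversible = FALSE, name = id) {
  stopifnot(is.character(id), nzchar(id))
  coef_to_rat <- function(x) {
    r <- rat_parse(format(x, scientific = FALSE, trim = TRUE))
    if (is.null(r)) stop("bad coefficient: ", x, call. = FALSE)
    r
  }
  rows <- list()
  for (side in c("reactant", "product")) {
    v <- if (side == "reactant") reactants else products
    if (length(v) == 0) next
    stopifnot(!is.null(names(v)), all(nzchar(names(v))), all(v > 0))
    for (i in seq_along(v)) {
      r <- coef_to_rat(v[[i]])
      rows[[length(rows) + 1L]] <-
        new_participants(names(v)[i], r$num, r$den, side)
    }
  }
  if (length(rows) == 0)
    stop("reaction needs at least one participant", call. = FALSE)
  structure(list(id = id, name = name,
                 participants = do.call(rbind, rows),
                 reversible = isTRUE(reversible),
                 annotations = list()),
            class = "mm_reaction")
}

#' Create an empty model
#'
#' @param id Model token.
#' @param compartments Named character vector `c(token = name)`; a default
#'   cytosol compartment `c` is always present.
#' @return Object of class `mm_model`.
#' @export
model <- function(id = "model", compartments = c(c = "cytosol")) {
  structure(list(id = id, metabolites = list(), reactions = list(),
                 compartments = compartments),
            class = "mm_model")
}

#' Add entities to a model
#'
#' `model_add_metabolite()` and `model_add_reaction()` insert entities,
#' enforcing unique ids and (for reactions) that every participant
#' metabolite exists. Unknown compartments are auto-declared.
#'
#' @param m An `mm_model`.
#' @param met An `mm_metabolite`.
#' @param rxn An `mm_reaction`.
#' @return The updated model.
#' @name model_add
NULL

#' @rdname model_add
#' @export
model_add_metabolite <- function(m, met) {
  stopifnot(inherits(m, "mm_model"), inherits(met, "mm_metabolite"))
  if (met$id %in% names(m$metabolites))
    stop("duplicate metabolite id: ", met$id, call. = FALSE)
  if (!met$compartment %in% names(m$compartments))
    m$compartments[met$compartment] <- met$compartment
  m$metabolites[[met$id]] <- met
  m
}

#' @rdname model_add
#' @export
model_add_reaction <- function(m, rxn) {
  stopifnot(inherits(m, "mm_model"), inherits(rxn, "mm_reaction"))
  if (rxn$id %in% names(m$reactions))
    stop("duplicate reaction id: ", rxn$id, call. = FALSE)
  missing <- setdiff(rxn$participants$metabolite, names(m$metabolites))
  if (length(missing) > 0)
    stop("reaction ", rxn$id, " references unknown metabolites: ",
         paste(missing, collapse = ", "), call. = FALSE)
  m$reactions[[rxn$id]] <- rxn
  m
}

#' Annotate a model entity in place
#'
#' Convenience wrapper around [add_annotation()] that looks the entity up by
#' id (metabolites first, then reactions) and stores the updated entity back
#' in the model.
#'
#' @param m An `mm_model`.
#' @param entity_id Metabolite or reaction id.
#' @param ann An `mm_annotation`.
#' @return The updated model, with attribute `added`.
#' @export
model_annotate <- function(m, entity_id, ann) {
  if (entity_id %in% names(m$metabolites)) {
    ent <- add_annotation(m$metabolites[[entity_id]], ann)
    added <- attr(ent, "added"); attr(ent, "added") <- NULL
    m$metabolites[[entity_id]] <- ent
  } else if (entity_id %in% names(m$reactions)) {
    ent <- add_annotation(m$reactions[[entity_id]], ann)
    added <- attr(ent, "added"); attr(ent, "added") <- NULL
    m$reactions[[entity_id]] <- ent
  } else {
    stop("no such entity: ", entity_id, call. = FALSE)
  }
  attr(m, "added") <- added
  m
}

#' @export
print.mm_metabolite <- function(x, ...) {
  cat(sprintf("<metabolite> %s (%s) [%s], %d annotation(s)\n",
              x$id, x$name, x$compartment, length(x$annotations)))
  invisible(x)
}

#' @export
print.mm_reaction <- function(x, ...) {
  arrow <- if (x$reversible) "<=>" else "->"
  sides <- split(x$participants, x$participants$side)
  fmt_side <- function(df) {
    if (is.null(df) || nrow(df) == 0) return("∅")
    paste(vapply(seq_len(nrow(df)), function(i) {
      cf <- if (df$num[i] == df$den[i]) "" else paste0(rat_format(df$num[i], df$den[i]), " ")
      paste0(cf, df$metabolite[i])
    }, character(1)), collapse = " + ")
  }
  cat(sprintf("<reaction> %s: %s %s %s\n", x$id,
              fmt_side(sides$reactant), arrow, fmt_side(sides$product)))
  invisible(x)
}

#' @export
print.mm_model <- function(x, ...) {
  cat(sprintf("<model> %s: %d metabolites, %d reactions, %d compartments\n",
              x$id, length(x$metabolites), length(x$reactions),
              length(x$compartments)))
  invisible(x)
}

# Structural + annotation equality up to annotation ordering; used by
# round-trip tests and the CLI.
model_equal <- function(a, b) {
  if (!setequal(names(a$metabolites), names(b$metabolites))) return(FALSE)
  if (!setequal(names(a$reactions), names(b$reactions))) return(FALSE)
  for (id in names(a$metabolites)) {
    ma <- a$metabolites[[id]]; mb <- b$metabolites[[id]]
    if (!identical(ma$name, mb$name)) return(FALSE)
    if (!identical(ma$compartment, mb$compartment)) return(FALSE)
    if (!identical(ann_multiset(ma), ann_multiset(mb))) return(FALSE)
  }
  for (id in names(a$reactions)) {
    ra <- a$reactions[[id]]; rb <- b$reactions[[id]]
    if (!identical(ra$reversible, rb$reversible)) return(FALSE)
    pa <- ra$participants[order(ra$participants$side, ra$participants$metabolite), ]
    pb <- rb$participants[order(rb$participants$side, rb$participants$metabolite), ]
    rownames(pa) <- rownames(pb) <- NULL
    if (!identical(pa, pb)) return(FALSE)
    if (!identical(ann_multiset(ra), ann_multiset(rb))) return(FALSE)
  }
  TRUE
}
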