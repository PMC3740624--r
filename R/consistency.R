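# Mass and charge balance per reaction; model-wide annotation report.
#
# Conservation of mass and charge across every reaction is a prerequisite
# for constraint-based analysis, and imbalances usually trace back to
# wrong protonation states or missing species. Arithmetic is exact
# (rational coefficients times integer element counts); reactions with a
# participant lacking a formula, or with generic placeholder elements
# (R/X/Z), are "undetermined" rather than balanced or imbalanced, and
# one-sided exchange reactions are exempt ("exchange").

balance_sides <- function(rxn, m, value_fn) {
  # returns signed rational totals per key: products minus reactants
  totals <- list()  # key -> c(num, den)
  for (i in seq_len(nrow(rxn$participants))) {
    p <- rxn$participants[i, ]
    vals <- value_fn(m$metabolites[[p$metabolite]])
    sgn <- if (p$side == "product") 1 else -1
    for (key in names(vals)) {
      contrib <- rat_mul(sgn * p$num, p$den, vals[[key]], 1)
      cur <- totals[[key]] %||% c(0, 1)
      r <- rat_add(cur[1], cur[2], contrib$num, contrib$den)
      totals[[key]] <- c(r$num, r$den)
    }
  }
  totals
}

#' Element balance of a reaction
#'
#' For each element, the signed total `sum(products) - sum(reactants)` of
#' coefficient times element count, computed in exact rational arithmetic.
#' An empty result means the reaction is mass-balanced.
#'
#' @param rxn An `mm_reaction` (or its id).
#' @param m The containing `mm_model`.
#' @return Named numeric vector of nonzero signed element deltas; empty
#'   when balanced. `NULL` when any participant lacks a usable formula
#'   (undetermined).
#' @examples
#' # atp + h2o -> adp + pi + h balances to an empty delta
#' @export
element_balance <- function(rxn, m) {
  if (is.character(rxn)) rxn <- m$reactions[[rxn]]
  formulas <- lapply(rxn$participants$metabolite, function(id)
    entity_formula(m$metabolites[[id]]))
  if (any(vapply(formulas, is.null, logical(1)))) return(NULL)
  if (any(vapply(formulas, function(f) ec_has_generic(f$formula), logical(1))))
    return(NULL)
  totals <- balance_sides(rxn, m, function(met) {
    f <- entity_formula(met)$formula
    as.list(f)
  })
  out <- vapply(totals, function(r) r[1] / r[2], numeric(1))
  out[out != 0]
}

#' Charge balance of a reaction
#'
#' Signed total `sum(products) - sum(reactants)` of coefficient times
#' charge; 0 means charge-balanced.
#'
#' @inheritParams element_balance
#' @return A number, or `NA` when any participant lacks a charge (unknown).
#' @export
charge_balance <- function(rxn, m) {
  if (is.character(rxn)) rxn <- m$reactions[[rxn]]
  charges <- lapply(rxn$participants$metabolite, function(id)
    entity_charge(m$metabolites[[id]]))
  if (any(vapply(charges, is.null, logical(1)))) return(NA_real_)
  totals <- balance_sides(rxn, m, function(met) list(q = entity_charge(met)))
  if (length(totals) == 0) return(0)
  totals$q[1] / totals$q[2]
}

#' Balance report for one reaction
#'
#' @inheritParams element_balance
#' @return List of class `mm_balance`: `reaction_id`, `status` (`balanced`,
#'   `imbalanced`, `undetermined`, `exchange`), `element_imbalance` (signed
#'   named vector), `charge_imbalance` (number or `NA`), and `missing`
#'   (metabolite ids lacking formula or charge).
#' @export
balance_report <- function(rxn, m) {
  if (is.character(rxn)) rxn <- m$reactions[[rxn]]
  sides <- unique(rxn$participants$side)
  missing <- character(0)
  for (id in unique(rxn$participants$metabolite)) {
    met <- m$metabolites[[id]]
    f <- entity_formula(met)
    if (is.null(f) || ec_has_generic(f$formula) || is.null(entity_charge(met)))
      missing <- c(missing, id)
  }
  if (length(sides) < 2) {
    return(structure(list(reaction_id = rxn$id, status = "exchange",
                          element_imbalance = NULL, charge_imbalance = NA_real_,
                          missing = missing), class = "mm_balance"))
  }
  eb <- element_balance(rxn, m)
  qb <- charge_balance(rxn, m)
  status <- if (is.null(eb) || is.na(qb)) "undetermined"
            else if (length(eb) == 0 && qb == 0) "balanced"
            else "imbalanced"
  structure(list(reaction_id = rxn$id, status = status,
                 element_imbalance = eb, charge_imbalance = qb,
                 missing = sort(missing)),
            class = "mm_balance")
}

#' Model-wide consistency report
#'
#' Aggregates per-reaction balance reports plus lists of metabolites
#' lacking any structure, metabolites lacking any cross reference, and
#' groups of metabolites sharing a normalized name. Ordering is
#' deterministic (by entity id).
#'
#' @param m An `mm_model`.
#' @return List of class `mm_report`: `balance` (list of `mm_balance`),
#'   `imbalanced`, `undetermined` (reaction id vectors),
#'   `missing_structure`, `missing_xref` (metabolite id vectors),
#'   `duplicate_names` (list of id vectors), `counts` (named integers).
#' @export
model_report <- function(m) {
  rxn_ids <- sort(names(m$reactions))
  balance <- lapply(rxn_ids, function(id) balance_report(m$reactions[[id]], m))
  names(balance) <- rxn_ids
  status <- vapply(balance, `[[`, character(1), "status")
  met_ids <- sort(names(m$metabolites))
  missing_structure <- met_ids[!vapply(met_ids, function(id)
    has_structure(m$metabolites[[id]]), logical(1))]
  missing_xref <- met_ids[vapply(met_ids, function(id)
    length(annotations(m$metabolites[[id]], "crossref")) == 0, logical(1))]
  norm <- vapply(met_ids, function(id)
    normalize_name(m$metabolites[[id]]$name), character(1))
  dup_groups <- unname(Filter(function(g) length(g) > 1,
                              split(met_ids, norm)))
  dup_groups <- lapply(dup_groups, sort)
  dup_groups <- dup_groups[order(vapply(dup_groups, `[[`, character(1), 1))]
  rep <- list(balance = balance,
              imbalanced = rxn_ids[status == "imbalanced"],
              undetermined = rxn_ids[status == "undetermined"],
              missing_structure = missing_structure,
              missing_xref = missing_xref,
              duplicate_names = dup_groups,
              counts = c(reactions = length(rxn_ids),
                         metabolites = length(met_ids),
                         imbalanced = sum(status == "imbalanced"),
                         undetermined = sum(status == "undetermined"),
                         exchange = sum(status == "exchange"),
                         missing_structure = length(missing_structure),
                         missing_xref = length(missing_xref),
                         duplicate_name_groups = length(dup_groups)))
  structure(rep, class = "mm_report")
}

#' @export
print.mm_balance <- function(x, ...) {
  cat(sprintf("%s: %s", x$reaction_id, x$status))
  if (!is.null(x$element_imbalance) && length(x$element_imbalance) > 0)
    cat("  elements:", paste(names(x$element_imbalance),
                             x$element_imbalance, sep = "", collapse = " "))
  if (!is.na(x$charge_imbalance) && x$charge_imbalance != 0)
    cat("  charge:", x$charge_imbalance)
  if (length(x$missing) > 0)
    cat("  missing:", paste(x$missing, collapse = ","))
  cat("\n")
  invisible(x)
}

#' @export
print.mm_report <- function(x, ...) {
  cat("Model consistency report\n")
  cat(sprintf("  reactions: %d (%d imbalanced, %d undetermined, %d exchange)\n",
              x$counts[["reactions"]], x$counts[["imbalanced"]],
              x$counts[["undetermined"]], x$counts[["exchange"]]))
  cat(sprintf("  metabolites: %d (%d without structure, %d without cross reference)\n",
              x$counts[["metabolites"]], x$counts[["missing_structure"]],
              x$counts[["missing_xref"]]))
  cat(sprintf("  duplicate-name groups: %d\n", x$counts[["duplicate_name_groups"]]))
  for (b in x$balance)
    if (b$status %in% c("imbalanced", "undetermined")) print(b)
  invisible(x)
}

# JSON-serializable form of a report (CLI output)
report_to_list <- function(rep) {
  list(
    counts = as.list(rep$counts),
    imbalanced = as.list(rep$imbalanced),
    undetermined = as.list(rep$undetermined),
    missing_structure = as.list(rep$missing_structure),
    missing_xref = as.list(rep$missing_xref),
    duplicate_names = lapply(rep$duplicate_names, as.list),
    reactions = lapply(rep$balance, function(b) list(
      status = b$status,
      element_imbalance = if (is.null(b$element_imbalance)) NULL
                          else as.list(b$element_imbalance),
      charge_imbalance = if (is.na(b$charge_imbalance)) NULL
                         else b$charge_imbalance,
      missing = as.list(b$missing))))
}
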