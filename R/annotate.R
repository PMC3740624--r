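# Structure-annotation procedures.
#
# Automated-to-manual gradient: transfer from imported notes, lookup by
# cross reference against the local index, exact/ranked name search, and
# peptide assembly from the metabolite name. Every action (including every
# refusal) is recorded as a decision; attachment never overwrites an
# existing structure -- conflicts surface as rejected decisions.

new_decision <- function(metabolite_id, method, chosen = NA_character_,
                         score = NA_real_, accepted = FALSE, rationale = "",
                         namespace = NA_character_, identifier = NA_character_) {
  if (method == "name_ranked" && is.na(score))
    stop("name_ranked decisions require a score", call. = FALSE)
  if (!accepted && !nzchar(rationale))
    stop("rejected decisions require a rationale", call. = FALSE)
  list(metabolite_id = metabolite_id, method = method, chosen = chosen,
       score = score, accepted = accepted, rationale = rationale,
       namespace = namespace, identifier = identifier)
}

record_formula <- function(rec) {
  if (!is.null(rec$formula)) return(parse_formula(rec$formula))
  if (!is.null(rec$structure)) return(structure_formula(rec$structure))
  NULL
}

# one comparable key per record structure: element counts when known,
# else the notation text
structure_conflict_key <- function(rec) {
  f <- record_formula(rec)
  if (!is.null(f)) return(format_formula(f))
  paste0(rec$inchi %||% "", "|", rec$smiles %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

attach_record_structure <- function(m, met_id, rec) {
  if (!is.null(rec$inchi))
    m <- model_annotate(m, met_id, ann_structure("inchi", rec$inchi))
  if (!is.null(rec$smiles))
    m <- model_annotate(m, met_id, ann_structure("smiles", rec$smiles))
  attr(m, "added") <- NULL
  m
}

#' Attach structures via cross-reference lookup
#'
#' For each metabolite lacking a structure but holding at least one cross
#' reference, the local index is queried per cross reference in annotation
#' order; the first hit carrying a structure is attached. When several
#' cross references resolve to structures with different element counts,
#' nothing is attached and the decision is rejected with rationale
#' `"conflict"`. Metabolites already holding a structure are skipped
#' entirely (idempotence).
#'
#' @param m An `mm_model`.
#' @param index An `mm_index`.
#' @return List with the updated `model` and `decisions`.
#' @export
annotate_by_xref <- function(m, index) {
  decisions <- list()
  for (met_id in names(m$metabolites)) {
    met <- m$metabolites[[met_id]]
    if (has_structure(met)) next
    xrefs <- annotations(met, "crossref")
    if (length(xrefs) == 0) next
    hits <- list()
    for (a in xrefs) {
      rec <- lookup_xref(index, list(namespace = a$namespace,
                                     identifier = a$identifier))
      if (!is.null(rec) && (!is.null(rec$inchi) || !is.null(rec$smiles)))
        hits[[length(hits) + 1L]] <- rec
    }
    if (length(hits) == 0) {
      decisions[[length(decisions) + 1L]] <- new_decision(
        met_id, "xref_lookup", accepted = FALSE,
        rationale = "no indexed structure for any cross reference")
      next
    }
    keys <- unique(vapply(hits, structure_conflict_key, character(1)))
    if (length(keys) > 1) {
      decisions[[length(decisions) + 1L]] <- new_decision(
        met_id, "xref_lookup", accepted = FALSE, rationale = "conflict",
        chosen = paste(vapply(hits, function(r)
          paste0(r$namespace, ":", r$identifier), character(1)), collapse = ";"))
      next
    }
    rec <- hits[[1]]
    m <- attach_record_structure(m, met_id, rec)
    decisions[[length(decisions) + 1L]] <- new_decision(
      met_id, "xref_lookup", accepted = TRUE,
      chosen = paste0(rec$namespace, ":", rec$identifier),
      rationale = "structure from indexed cross reference",
      namespace = rec$namespace, identifier = rec$identifier)
  }
  list(model = m, decisions = decisions)
}

#' Attach structures and references by name search
#'
#' Silent mode attaches only unique exact normalized-name hits (method
#' `name_exact`, score 1.0): the record's cross reference is added and its
#' structure attached when present. Ambiguous exact hits (two or more
#' records sharing the normalized name) are never silently attached -- they
#' yield an unaccepted decision listing all candidates. Suggest mode
#' performs a ranked search and returns candidates scoring at least
#' `threshold` as unaccepted `name_ranked` decisions for review; nothing is
#' attached without confirmation (see [apply_decisions()]).
#'
#' @param m An `mm_model`.
#' @param index An `mm_index`.
#' @param mode `"silent"` or `"suggest"`.
#' @param threshold Minimum ranked score in (0, 1].
#' @param k Maximum ranked candidates per metabolite.
#' @return List with the updated `model` and `decisions`.
#' @export
annotate_by_name <- function(m, index, mode = c("silent", "suggest"),
                             threshold = 0.5, k = 5) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold <= 1)
  decisions <- list()
  for (met_id in names(m$metabolites)) {
    met <- m$metabolites[[met_id]]
    if (has_structure(met)) next
    if (mode == "silent") {
      hits <- search_exact(index, met$name)
      if (length(hits) == 0) next
      if (length(hits) > 1) {
        decisions[[length(decisions) + 1L]] <- new_decision(
          met_id, "name_exact", accepted = FALSE,
          rationale = "ambiguous exact name match",
          chosen = paste(vapply(hits, function(r)
            paste0(r$namespace, ":", r$identifier), character(1)), collapse = ";"))
        next
      }
      rec <- hits[[1]]
      xref_present <- any(vapply(annotations(met, "crossref"), function(a)
        a$namespace == rec$namespace && a$identifier == rec$identifier,
        logical(1)))
      rec_has_structure <- !is.null(rec$inchi) || !is.null(rec$smiles)
      if (xref_present && !rec_has_structure) next  # nothing new to add
      m <- model_annotate(m, met_id, ann_crossref(rec$namespace, rec$identifier))
      m <- attach_record_structure(m, met_id, rec)
      attr(m, "added") <- NULL
      decisions[[length(decisions) + 1L]] <- new_decision(
        met_id, "name_exact", accepted = TRUE, score = 1,
        chosen = paste0(rec$namespace, ":", rec$identifier),
        rationale = "unique exact name match",
        namespace = rec$namespace, identifier = rec$identifier)
    } else {
      ranked <- search_ranked(index, met$name, k)
      for (cand in ranked) {
        if (cand$score < threshold) next
        decisions[[length(decisions) + 1L]] <- new_decision(
          met_id, "name_ranked", accepted = FALSE, score = cand$score,
          rationale = "candidate awaiting confirmation",
          chosen = paste0(cand$record$namespace, ":", cand$record$identifier),
          namespace = cand$record$namespace, identifier = cand$record$identifier)
      }
    }
  }
  list(model = m, decisions = decisions)
}

#' Transfer annotations from imported notes
#'
#' Works on models imported with raw notes retained (see
#' `read_sbml(extract_notes = FALSE)`): every `note` annotation line
#' matching the dialect is promoted to its typed annotation (structure,
#' formula, charge, cross reference, synonym) and logged as a
#' `notes_transfer` decision. Structure lines are not applied to
#' metabolites already holding a structure; a notes formula contradicting
#' the formula of an existing structure yields a rejected decision with
#' rationale `"conflict"`. Malformed lines become rejected decisions.
#'
#' @param m An `mm_model`.
#' @param dialect Notes alias table, see [notes_dialect()].
#' @param registry An `mm_registry`.
#' @return List with the updated `model` and `decisions`.
#' @export
transfer_structures <- function(m, dialect = notes_dialect(),
                                registry = read_registry()) {
  decisions <- list()
  for (met_id in names(m$metabolites)) {
    met <- m$metabolites[[met_id]]
    notes <- annotations(met, "note")
    if (length(notes) == 0) next
    text <- paste(vapply(notes, `[[`, character(1), "value"), collapse = "\n")
    res <- extract_notes_annotations(text, dialect, registry)
    for (w in res$warnings)
      decisions[[length(decisions) + 1L]] <- new_decision(
        met_id, "notes_transfer", accepted = FALSE, rationale = w)
    for (a in res$annotations) {
      if (a$kind == "structure" && has_structure(m$metabolites[[met_id]])) {
        existing <- annotations(m$metabolites[[met_id]], "structure")
        if (!any(vapply(existing, function(e) ann_key(e) == ann_key(a), logical(1))))
          decisions[[length(decisions) + 1L]] <- new_decision(
            met_id, "notes_transfer", accepted = FALSE, rationale = "conflict",
            chosen = ann_key(a))
        next
      }
      if (a$kind == "formula") {
        ef <- entity_formula(m$metabolites[[met_id]])
        if (!is.null(ef) && ef$source == "structure" &&
            !ec_equal(ef$formula, a$formula)) {
          decisions[[length(decisions) + 1L]] <- new_decision(
            met_id, "notes_transfer", accepted = FALSE, rationale = "conflict",
            chosen = ann_key(a))
          next
        }
      }
      m <- model_annotate(m, met_id, a)
      added <- attr(m, "added"); attr(m, "added") <- NULL
      if (isTRUE(added))
        decisions[[length(decisions) + 1L]] <- new_decision(
          met_id, "notes_transfer", accepted = TRUE, chosen = ann_key(a),
          rationale = "transferred from notes")
    }
  }
  list(model = m, decisions = decisions)
}

#' Assemble peptide structures from metabolite names
#'
#' For each structure-less metabolite whose name parses as a peptide of at
#' least two residues (see [parse_peptide_name()]), the condensation
#' structure from [assemble_peptide()] is attached together with its
#' formula and neutral charge.
#'
#' @param m An `mm_model`.
#' @param table Residue table from [residue_table()].
#' @return List with the updated `model` and `decisions`.
#' @export
annotate_peptides <- function(m, table = residue_table()) {
  decisions <- list()
  for (met_id in names(m$metabolites)) {
    met <- m$metabolites[[met_id]]
    if (has_structure(met)) next
    resid <- parse_peptide_name(met$name, table)
    if (is.null(resid) || length(resid) < 2) next
    s <- assemble_peptide(as.character(resid), table)
    m <- model_annotate(m, met_id, ann_structure("smiles", s$smiles))
    m <- model_annotate(m, met_id, ann_formula(s$formula))
    m <- model_annotate(m, met_id, ann_charge(s$charge))
    attr(m, "added") <- NULL
    decisions[[length(decisions) + 1L]] <- new_decision(
      met_id, "peptide_assembly", accepted = TRUE,
      chosen = paste(resid, collapse = "-"),
      rationale = "peptide assembled from name")
  }
  list(model = m, decisions = decisions)
}

#' Attach a structure from a file (manual attachment)
#'
#' Headless counterpart of manually attaching a structure to one
#' metabolite: reads a structure file (plain InChI or SMILES text, or an
#' MDL MOL/SDF file, from which only an InChI/SMILES tag field is taken)
#' and attaches it if the metabolite has no structure yet.
#'
#' @param m An `mm_model`.
#' @param metabolite_id Target metabolite id.
#' @param path Structure file.
#' @return List with the updated `model` and `decisions`.
#' @export
attach_structure_file <- function(m, metabolite_id, path) {
  if (!metabolite_id %in% names(m$metabolites))
    stop("no such metabolite: ", metabolite_id, call. = FALSE)
  if (has_structure(m$metabolites[[metabolite_id]]))
    return(list(model = m, decisions = list(new_decision(
      metabolite_id, "manual_file", accepted = FALSE,
      rationale = "metabolite already has a structure"))))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  ann <- NULL
  inchi <- grep("^InChI=", lines, value = TRUE)
  if (length(inchi) > 0) {
    ann <- ann_structure("inchi", inchi[1])
  } else if (length(lines) == 1) {
    ann <- ann_structure("smiles", lines[1])
  }
  if (is.null(ann))
    return(list(model = m, decisions = list(new_decision(
      metabolite_id, "manual_file", accepted = FALSE,
      rationale = "no InChI or single-line SMILES found in file"))))
  m <- model_annotate(m, metabolite_id, ann)
  attr(m, "added") <- NULL
  list(model = m, decisions = list(new_decision(
    metabolite_id, "manual_file", accepted = TRUE, chosen = ann_key(ann),
    rationale = paste("attached from", basename(path)))))
}

#' Run the full annotation pipeline
#'
#' Fixed default order mirroring the automated-to-manual gradient:
#' notes transfer, then cross-reference lookup, then name search, then
#' peptide assembly; the order is overridable. All steps are idempotent on
#' the model: a second run produces zero new accepted decisions.
#'
#' @param m An `mm_model`.
#' @param index An `mm_index`.
#' @param mode Name-search mode, `"silent"` or `"suggest"`.
#' @param threshold Ranked-candidate threshold.
#' @param order Steps to run, subset of
#'   `c("transfer", "xref", "name", "peptide")`.
#' @param dialect,registry,residues Step configuration.
#' @return List with the annotated `model` and all `decisions`.
#' @export
annotate_model <- function(m, index, mode = "silent", threshold = 0.5,
                           order = c("transfer", "xref", "name", "peptide"),
                           dialect = notes_dialect(),
                           registry = read_registry(),
                           residues = residue_table()) {
  decisions <- list()
  for (step in order) {
    res <- switch(step,
      transfer = transfer_structures(m, dialect, registry),
      xref = annotate_by_xref(m, index),
      name = annotate_by_name(m, index, mode, threshold),
      peptide = annotate_peptides(m, residues),
      stop("unknown pipeline step: ", step, call. = FALSE))
    m <- res$model
    decisions <- c(decisions, res$decisions)
  }
  list(model = m, decisions = decisions)
}

#' Confirm and apply reviewed decisions
#'
#' Applies decisions whose `accepted` flag has been switched to `TRUE`
#' during review (the headless counterpart of interactive candidate
#' selection): the referenced index record's cross reference and structure
#' are attached, still refusing to overwrite existing structures.
#'
#' @param m An `mm_model`.
#' @param decisions Decision list (e.g. from [read_decision_log()]).
#' @param index An `mm_index`.
#' @return List with the updated `model` and the decisions actually applied.
#' @export
apply_decisions <- function(m, decisions, index) {
  applied <- list()
  for (d in decisions) {
    if (!isTRUE(d$accepted)) next
    if (is.na(d$namespace) || is.na(d$identifier)) next
    rec <- lookup_xref(index, list(namespace = d$namespace,
                                   identifier = d$identifier))
    if (is.null(rec)) next
    if (has_structure(m$metabolites[[d$metabolite_id]])) next
    m <- model_annotate(m, d$metabolite_id,
                        ann_crossref(rec$namespace, rec$identifier))
    m <- attach_record_structure(m, d$metabolite_id, rec)
    attr(m, "added") <- NULL
    applied[[length(applied) + 1L]] <- d
  }
  list(model = m, decisions = applied)
}

#' Write / read a decision log
#'
#' Machine-auditable provenance: one JSON object per line, one line per
#' decision.
#'
#' @param decisions Decision list.
#' @param path Log file path.
#' @return `write_decision_log`: invisibly the path; `read_decision_log`:
#'   the decision list.
#' @export
write_decision_log <- function(decisions, path) {
  lines <- vapply(decisions, function(d)
    as.character(jsonlite::toJSON(d, auto_unbox = TRUE, null = "null",
                                  na = "null", digits = NA)),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_decision_log
#' @export
read_decision_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lapply(lines[nzchar(lines)], function(l) {
    d <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    for (f in c("chosen", "namespace", "identifier"))
      if (is.null(d[[f]])) d[[f]] <- NA_character_
    if (is.null(d$score)) d$score <- NA_real_
    d
  })
}
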