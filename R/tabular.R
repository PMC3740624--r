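# Spreadsheet import (CSV/TSV) with an explicit column mapping.
#
# The mapping is user configuration, never positional guessing: a JSON (or
# R list) naming, for each sheet role, which column label carries each
# semantic field. Metabolite sheet fields: id (required), name, formula,
# charge, compartment, inchi, smiles, synonyms, xref:<namespace>. Reaction
# sheet fields: id (required), equation (required), name, reversible.

#' Read a column-mapping configuration
#'
#' @param path JSON file with shape
#'   `{"metabolites": {"id": "Abbreviation", ...}, "reactions": {...}}`.
#' @return List with `metabolites` and `reactions` named character vectors.
#' @export
read_mapping <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_mapping(cfg)
}

map_get <- function(map, field) {
  if (is.null(map) || !field %in% names(map)) NULL else map[[field]]
}

validate_mapping <- function(cfg) {
  if (is.null(map_get(cfg$metabolites, "id")))
    stop("mapping: metabolite id column not mapped", call. = FALSE)
  if (!is.null(cfg$reactions)) {
    if (is.null(map_get(cfg$reactions, "id")) ||
        is.null(map_get(cfg$reactions, "equation")))
      stop("mapping: reaction id and equation columns must be mapped", call. = FALSE)
  }
  cfg
}

read_delim_auto <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"", comment.char = "",
                    colClasses = "character")
}

slugify_id <- function(x) {
  s <- gsub("[^A-Za-z0-9_]+", "_", trimws(x))
  s <- gsub("^_+|_+$", "", s)
  if (!grepl("^[A-Za-z_]", s)) s <- paste0("m_", s)
  s
}

#' Import a model from metabolite and reaction tables
#'
#' Reads delimited (CSV or TSV) sheets under an explicit [read_mapping()]
#' column mapping. One metabolite per metabolite-sheet row; reaction
#' equations are parsed with [parse_equation()] and participant names
#' resolved against metabolite ids first, then display names. Metabolites
#' referenced only in equations are auto-created with a warning.
#' Cross-reference columns are validated against the registry.
#'
#' @param metabolite_table Path to the metabolite sheet.
#' @param reaction_table Path to the reaction sheet, or `NULL`.
#' @param mapping Column mapping (list, see [read_mapping()]).
#' @param registry An `mm_registry`.
#' @param default_compartment Compartment token applied when a row or an
#'   equation term names none.
#' @return An `mm_model`, with attribute `warnings`.
#' @export
read_tabular <- function(metabolite_table, reaction_table = NULL, mapping,
                         registry = read_registry(),
                         default_compartment = "c") {
  mapping <- validate_mapping(mapping)
  warnings_out <- character(0)
  mt <- read_delim_auto(metabolite_table)
  mmap <- mapping$metabolites
  for (lab in unlist(mmap))
    if (!lab %in% names(mt))
      stop("mapped column '", lab, "' missing from metabolite table", call. = FALSE)

  ids <- trimws(mt[[map_get(mmap, "id")]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop("duplicate metabolite ids: ", paste(dup, collapse = ", "), call. = FALSE)

  get_col <- function(map, df, field, i) {
    lab <- map_get(map, field)
    if (is.null(lab)) return(NA_character_)
    v <- trimws(df[[lab]][i])
    if (!nzchar(v)) NA_character_ else v
  }

  m <- model("tabular_model", stats::setNames(default_compartment, default_compartment))
  for (i in seq_along(ids)) {
    nm <- get_col(mmap, mt, "name", i)
    comp <- get_col(mmap, mt, "compartment", i)
    met <- metabolite(ids[i], if (is.na(nm)) ids[i] else nm,
                      if (is.na(comp)) default_compartment else comp)
    f <- get_col(mmap, mt, "formula", i)
    if (!is.na(f)) met <- add_annotation(met, ann_formula(f))
    q <- get_col(mmap, mt, "charge", i)
    if (!is.na(q)) met <- add_annotation(met, ann_charge(as.integer(q)))
    for (notation in c("inchi", "smiles")) {
      v <- get_col(mmap, mt, notation, i)
      if (!is.na(v)) met <- add_annotation(met, ann_structure(notation, v))
    }
    syn <- get_col(mmap, mt, "synonyms", i)
    if (!is.na(syn))
      for (s in strsplit(syn, "|", fixed = TRUE)[[1]])
        if (nzchar(trimws(s))) met <- add_annotation(met, ann_synonym(trimws(s)))
    for (field in grep("^xref:", names(mmap), value = TRUE)) {
      v <- get_col(mmap, mt, field, i)
      if (is.na(v)) next
      ns <- sub("^xref:", "", field)
      x <- tryCatch(xref(ns, v, registry), error = function(e) NULL)
      if (is.null(x)) {
        warnings_out <- c(warnings_out,
                          sprintf("row %d: invalid %s identifier '%s'", i, ns, v))
      } else {
        met <- add_annotation(met, ann_crossref(x$namespace, x$identifier))
      }
    }
    attr(met, "added") <- NULL
    m <- model_add_metabolite(m, met)
  }

  if (!is.null(reaction_table)) {
    rt <- read_delim_auto(reaction_table)
    rmap <- mapping$reactions
    for (lab in unlist(rmap))
      if (!lab %in% names(rt))
        stop("mapped column '", lab, "' missing from reaction table", call. = FALSE)
    rids <- trimws(rt[[map_get(rmap, "id")]])
    dup <- unique(rids[duplicated(rids)])
    if (length(dup) > 0)
      stop("duplicate reaction ids: ", paste(dup, collapse = ", "), call. = FALSE)
    name_to_id <- stats::setNames(
      names(m$metabolites),
      vapply(m$metabolites, `[[`, character(1), "name"))
    for (i in seq_along(rids)) {
      eq <- parse_equation(rt[[map_get(rmap, "equation")]][i])
      parts <- eq$participants
      met_ids <- character(nrow(parts))
      for (j in seq_len(nrow(parts))) {
        token <- parts$name[j]
        if (token %in% names(m$metabolites)) {
          met_ids[j] <- token
        } else if (token %in% names(name_to_id)) {
          met_ids[j] <- name_to_id[[token]]
        } else {
          new_id <- slugify_id(token)
          comp <- if (is.na(parts$compartment[j])) default_compartment
                  else parts$compartment[j]
          m <- model_add_metabolite(m, metabolite(new_id, token, comp))
          name_to_id[token] <- new_id
          warnings_out <- c(warnings_out,
                            sprintf("metabolite '%s' auto-created from equation of %s",
                                    token, rids[i]))
          met_ids[j] <- new_id
        }
      }
      rxn <- structure(
        list(id = rids[i],
             name = { lab <- map_get(rmap, "name")
                      nm <- if (!is.null(lab)) trimws(rt[[lab]][i]) else ""
                      if (nzchar(nm)) nm else rids[i] },
             participants = new_participants(met_ids, parts$num, parts$den, parts$side),
             reversible = eq$reversible, annotations = list()),
        class = "mm_reaction")
      m <- model_add_reaction(m, rxn)
    }
  }
  for (w in warnings_out) warning(w, call. = FALSE)
  attr(m, "warnings") <- warnings_out
  m
}
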