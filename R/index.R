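# Local, offline searchable index over chemical resource tables.
#
# Records come from delimited tables (identifier, name, "|"-separated
# synonyms, formula, charge, inchi, smiles) declared per-namespace, or from
# SDF-style records through a thin tag-field adapter. Queries: exact
# normalized-name match, ranked fuzzy match (character-trigram Jaccard on
# normalized names), and exact xref lookup. Builds are deterministic:
# identical tables and config serialize byte-identically.

GREEK_MAP <- c("α" = "alpha", "β" = "beta", "γ" = "gamma",
               "δ" = "delta", "ε" = "epsilon", "ω" = "omega",
               "Α" = "alpha", "Β" = "beta", "Γ" = "gamma",
               "Δ" = "delta", "Ε" = "epsilon", "Ω" = "omega")

#' Normalize a chemical name for matching
#'
#' Case-folds, maps Greek letters to their spelled names (`α` to
#' `alpha`), collapses runs of whitespace, hyphens, commas and parentheses
#' to single spaces and strips leading/trailing space. Idempotent.
#'
#' @param text Name text.
#' @return Normalized name.
#' @examples
#' normalize_name("D-Glucose 6-phosphate")
#' normalize_name("α-D-glucose")
#' @export
normalize_name <- function(text) {
  stopifnot(is.character(text))
  out <- tolower(text)
  for (g in names(GREEK_MAP))
    out <- gsub(g, paste0(" ", GREEK_MAP[[g]], " "), out, fixed = TRUE)
  out <- gsub("[-,()\\s]+", " ", out, perl = TRUE)
  trimws(out)
}

name_trigrams <- function(normalized) {
  n <- nchar(normalized)
  if (n < 3) return(character(0))
  unique(vapply(seq_len(n - 2), function(i) substr(normalized, i, i + 2),
                character(1)))
}

trigram_jaccard <- function(a, b) {
  if (identical(a, b)) return(1)
  ta <- name_trigrams(a); tb <- name_trigrams(b)
  if (length(ta) == 0 || length(tb) == 0) return(0)
  length(intersect(ta, tb)) / length(union(ta, tb))
}

#' Read a chemical resource table
#'
#' Delimited (CSV/TSV) table with a declared namespace and column labels.
#' Recognized columns: `identifier` (required), `name` (required),
#' `synonyms` (`|`-separated), `formula`, `charge`, `inchi`, `smiles`.
#' Custom labels are declared in `columns`.
#'
#' @param path Table file path.
#' @param namespace Registry namespace for the table's identifiers.
#' @param registry An `mm_registry`.
#' @param columns Named character vector mapping semantic field to column
#'   label; defaults to the semantic names themselves.
#' @return List of resource records plus warnings, ready for
#'   [build_index()].
#' @export
read_resource_table <- function(path, namespace, registry = read_registry(),
                                columns = NULL) {
  entry <- registry_entry(registry, namespace)  # errors on unknown namespace
  df <- read_delim_auto(path)
  lab <- function(field, default = field) {
    if (!is.null(columns) && field %in% names(columns)) columns[[field]] else default
  }
  for (field in c("identifier", "name"))
    if (!lab(field) %in% names(df))
      stop("resource table missing column '", lab(field), "'", call. = FALSE)
  opt <- function(field, i) {
    l <- lab(field)
    if (!l %in% names(df)) return(NA_character_)
    v <- trimws(df[[l]][i])
    if (!nzchar(v)) NA_character_ else v
  }
  records <- list(); warnings <- character(0)
  for (i in seq_len(nrow(df))) {
    id <- trimws(df[[lab("identifier")]][i])
    canon <- canonical_identifier(id, entry)
    if (is.null(canon)) {
      warnings <- c(warnings,
                    sprintf("%s row %d: identifier '%s' fails pattern, skipped",
                            namespace, i, id))
      next
    }
    syn <- opt("synonyms", i)
    syns <- if (is.na(syn)) character(0) else
      Filter(nzchar, trimws(strsplit(syn, "|", fixed = TRUE)[[1]]))
    f <- opt("formula", i)
    q <- opt("charge", i)
    inchi <- opt("inchi", i); smiles <- opt("smiles", i)
    struct <- if (!is.na(inchi) || !is.na(smiles)) {
      chemical_structure(inchi = if (is.na(inchi)) NULL else inchi,
                         smiles = if (is.na(smiles)) NULL else smiles,
                         formula = if (is.na(f)) NULL else f,
                         charge = if (is.na(q)) NULL else as.integer(q))
    } else NULL
    records[[length(records) + 1L]] <- list(
      namespace = entry$namespace, identifier = canon,
      primary_name = trimws(df[[lab("name")]][i]),
      synonyms = as.character(syns),
      formula = if (is.na(f)) NULL else format_formula(parse_formula(f)),
      charge = if (is.na(q)) NULL else as.integer(q),
      inchi = if (is.na(inchi)) NULL else inchi,
      smiles = if (is.na(smiles)) NULL else smiles,
      structure = struct)
  }
  list(records = records, warnings = warnings)
}

#' Read SDF-style records as a resource table
#'
#' Thin adapter for MDL SDF files: each record's tag fields are mapped to
#' the same semantic fields as [read_resource_table()] (`identifier`,
#' `name`, `synonyms`, `formula`, `charge`, `inchi`, `smiles`). The molfile
#' block itself is not interpreted.
#'
#' @param path SDF file path.
#' @param namespace Registry namespace for the identifiers.
#' @param registry An `mm_registry`.
#' @param tags Named character vector mapping semantic field to SDF tag
#'   name, e.g. `c(identifier = "ChEBI ID", name = "ChEBI Name")`.
#' @return Same shape as [read_resource_table()].
#' @export
read_sdf_records <- function(path, namespace, registry = read_registry(),
                             tags = c(identifier = "ID", name = "NAME")) {
  entry <- registry_entry(registry, namespace)
  text <- readLines(path, warn = FALSE)
  rec_bounds <- c(0, which(text == "$$$$"))
  records <- list(); warnings <- character(0)
  for (k in seq_len(length(rec_bounds) - 1)) {
    block <- text[(rec_bounds[k] + 1):(rec_bounds[k + 1] - 1)]
    fields <- list()
    i <- 1
    while (i <= length(block)) {
      m <- regmatches(block[i], regexec("^> *<(.+)>", block[i]))[[1]]
      if (length(m) == 2) {
        vals <- character(0); i <- i + 1
        while (i <= length(block) && nzchar(trimws(block[i]))) {
          vals <- c(vals, trimws(block[i])); i <- i + 1
        }
        fields[[m[2]]] <- paste(vals, collapse = "|")
      }
      i <- i + 1
    }
    get <- function(field) {
      tag <- if (field %in% names(tags)) tags[[field]] else NULL
      if (is.null(tag) || is.null(fields[[tag]])) NA_character_ else fields[[tag]]
    }
    id <- get("identifier")
    if (is.na(id)) { warnings <- c(warnings, sprintf("SDF record %d: no identifier tag", k)); next }
    canon <- canonical_identifier(id, entry)
    if (is.null(canon)) {
      warnings <- c(warnings, sprintf("SDF record %d: identifier '%s' fails pattern", k, id))
      next
    }
    syn <- get("synonyms")
    f <- get("formula"); q <- get("charge")
    inchi <- get("inchi"); smiles <- get("smiles")
    records[[length(records) + 1L]] <- list(
      namespace = entry$namespace, identifier = canon,
      primary_name = if (is.na(get("name"))) canon else get("name"),
      synonyms = if (is.na(syn)) character(0) else
        Filter(nzchar, trimws(strsplit(syn, "|", fixed = TRUE)[[1]])),
      formula = if (is.na(f)) NULL else format_formula(parse_formula(f)),
      charge = if (is.na(q)) NULL else as.integer(q),
      inchi = if (is.na(inchi)) NULL else inchi,
      smiles = if (is.na(smiles)) NULL else smiles,
      structure = if (!is.na(inchi) || !is.na(smiles))
        chemical_structure(inchi = if (is.na(inchi)) NULL else inchi,
                           smiles = if (is.na(smiles)) NULL else smiles,
                           formula = if (is.na(f)) NULL else f,
                           charge = if (is.na(q)) NULL else as.integer(q))
        else NULL)
  }
  list(records = records, warnings = warnings)
}

#' Build a searchable resource index
#'
#' Merges one or more resource tables (outputs of [read_resource_table()]
#' or [read_sdf_records()]) into a single index with maps from normalized
#' primary names/synonyms and from name trigrams to record positions.
#'
#' @param tables List of table objects, each with a `records` field.
#' @param registry An `mm_registry`.
#' @return Object of class `mm_index`, with attribute `warnings`.
#' @export
build_index <- function(tables, registry = read_registry()) {
  if (!is.null(tables$records)) tables <- list(tables)  # single table given
  records <- list(); warnings <- character(0)
  for (tb in tables) {
    records <- c(records, tb$records)
    warnings <- c(warnings, tb$warnings)
  }
  name_map <- list(); trigram_map <- list(); xref_map <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    norm_names <- unique(normalize_name(c(rec$primary_name, rec$synonyms)))
    records[[i]]$norm_names <- norm_names
    for (nn in norm_names) {
      name_map[[nn]] <- c(name_map[[nn]], i)
      for (tg in name_trigrams(nn)) trigram_map[[tg]] <- c(trigram_map[[tg]], i)
    }
    xref_map[[paste0(rec$namespace, "|", rec$identifier)]] <- i
  }
  idx <- structure(list(records = records, name_map = name_map,
                        trigram_map = lapply(trigram_map, unique),
                        xref_map = xref_map,
                        registry_version = registry$version),
                   class = "mm_index")
  attr(idx, "warnings") <- warnings
  idx
}

#' Exact name search
#'
#' Returns all records whose normalized primary name or synonym equals the
#' normalized query (see [normalize_name()]); empty list when none match.
#'
#' @param index An `mm_index`.
#' @param name Query name.
#' @return List of resource records.
#' @export
search_exact <- function(index, name) {
  ids <- index$name_map[[normalize_name(name)]]
  if (is.null(ids)) return(list())
  index$records[unique(ids)]
}

#' Ranked fuzzy name search
#'
#' Scores every candidate record by the Jaccard similarity of the
#' character-trigram sets of normalized names, taking the maximum over
#' primary name and synonyms. An exact normalized match scores 1.0 and
#' ranks first. Results are sorted by score descending with ties broken by
#' namespace then identifier; zero-score records are excluded and at most
#' `k` results returned. Queries shorter than three characters fall back to
#' exact matching only.
#'
#' @param index An `mm_index`.
#' @param name Query name.
#' @param k Maximum number of results (>= 1).
#' @return List of `list(record =, score =)` pairs.
#' @export
search_ranked <- function(index, name, k = 10) {
  stopifnot(k >= 1)
  q <- normalize_name(name)
  qt <- name_trigrams(q)
  if (length(qt) == 0) {  # short query: exact fallback
    hits <- search_exact(index, name)
    hits <- hits[seq_len(min(k, length(hits)))]
    return(lapply(hits, function(r) list(record = r, score = 1)))
  }
  cand <- unique(unlist(index$trigram_map[qt], use.names = FALSE))
  exact_ids <- index$name_map[[q]]
  cand <- unique(c(exact_ids, cand))
  if (length(cand) == 0) return(list())
  scored <- lapply(cand, function(i) {
    rec <- index$records[[i]]
    s <- max(vapply(rec$norm_names, function(nn) {
      if (identical(nn, q)) 1 else trigram_jaccard(q, nn)
    }, numeric(1)))
    list(record = rec, score = s)
  })
  scored <- Filter(function(x) x$score > 0, scored)
  ord <- order(-vapply(scored, `[[`, numeric(1), "score"),
               vapply(scored, function(x) x$record$namespace, character(1)),
               vapply(scored, function(x) x$record$identifier, character(1)))
  scored <- scored[ord]
  scored[seq_len(min(k, length(scored)))]
}

#' Exact cross-reference lookup
#'
#' Strict `(namespace, identifier)` match; identifier canonicalization
#' (e.g. inserting `CHEBI:`) is the caller's job via [xref()].
#'
#' @param index An `mm_index`.
#' @param x An `mm_xref` or list with `namespace` and `identifier`.
#' @return A resource record, or `NULL` when absent.
#' @export
lookup_xref <- function(index, x) {
  i <- index$xref_map[[paste0(x$namespace, "|", x$identifier)]]
  if (is.null(i)) NULL else index$records[[i]]
}

#' Persist / load a resource index
#'
#' The index is stored as a single self-describing JSON file with a format
#' and version header. Rebuilding from the same tables reproduces the file
#' byte-identically, so index builds are cacheable.
#'
#' @param index An `mm_index`.
#' @param path Output (or input) path.
#' @return `write_index`: invisibly the path; `read_index`: an `mm_index`.
#' @export
write_index <- function(index, path) {
  payload <- list(
    format = "metanno-index", version = 1L,
    registry_version = index$registry_version,
    records = lapply(index$records, function(r)
      r[c("namespace", "identifier", "primary_name", "synonyms",
          "formula", "charge", "inchi", "smiles")]))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null",
                           digits = NA, pretty = FALSE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(raw$format, "metanno-index"))
    stop("not a metanno index file: ", path, call. = FALSE)
  records <- lapply(raw$records, function(r) {
    r$synonyms <- as.character(unlist(r$synonyms))
    r$structure <- if (!is.null(r$inchi) || !is.null(r$smiles))
      chemical_structure(inchi = r$inchi, smiles = r$smiles,
                         formula = r$formula, charge = r$charge)
      else NULL
    r
  })
  idx <- build_index(list(list(records = records, warnings = character(0))))
  idx$registry_version <- raw$registry_version
  idx
}

#' @export
print.mm_index <- function(x, ...) {
  cat(sprintf("<resource index> %d records, %d distinct names, %d trigrams\n",
              length(x$records), length(x$name_map), length(x$trigram_map)))
  invisible(x)
}
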