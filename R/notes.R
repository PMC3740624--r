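# SBML notes dialect: "KEY: value" lines inside <notes> bodies.
#
# Published models encode formula/charge/structure and even cross
# references in free-text notes (COBRA-style). The dialect maps key aliases
# to semantic fields; it is a superset of common COBRA keys and user
# extensible. Each alias maps to exactly one field.

#' Default notes key dialect
#'
#' Named character vector mapping an upper-cased notes key alias to a
#' semantic field: `formula`, `charge`, `inchi`, `smiles`, `synonym`,
#' `note`, or `xref:<namespace>`. Extend or override by concatenating your
#' own entries, e.g. `c(notes_dialect(), MNX = "xref:metanetx.chemical")`.
#'
#' @return Named character vector (alias -> field).
#' @examples
#' notes_dialect()[["FORMULA"]]
#' @export
notes_dialect <- function() {
  c(FORMULA = "formula", CHEMICAL_FORMULA = "formula",
    CHARGE = "charge",
    INCHI = "inchi", SMILES = "smiles",
    KEGG = "xref:kegg.compound", KEGG_ID = "xref:kegg.compound",
    CHEBI = "xref:chebi", CHEBI_ID = "xref:chebi",
    HMDB = "xref:hmdb", HMDB_ID = "xref:hmdb",
    PUBCHEM = "xref:pubchem.compound", PUBCHEM_ID = "xref:pubchem.compound",
    METACYC = "xref:metacyc.compound",
    SYNONYM = "synonym", SYNONYMS = "synonym",
    NOTE = "note")
}

#' Extract annotations from SBML notes text
#'
#' Parses the body text of an SBML `notes` element line by line. Each
#' `"KEY: value"` line whose key matches a dialect alias yields the
#' corresponding annotation; cross-reference values are validated against
#' the registry before acceptance and invalid ones are reported as warnings,
#' never silently kept. Unmatched lines are ignored unless
#' `keep_unmatched = TRUE`, in which case they become `note` annotations
#' (used by the SBML reader so nothing is dropped).
#'
#' @param notes_text Character scalar (lines separated by newlines) or
#'   character vector of lines.
#' @param dialect Alias table from [notes_dialect()].
#' @param registry An `mm_registry` for cross-reference validation.
#' @param keep_unmatched Keep unmatched lines as `note` annotations?
#' @return List with `annotations` (list of `mm_annotation`) and `warnings`
#'   (character vector).
#' @examples
#' extract_notes_annotations("FORMULA: C4H8N2O3\nCHARGE: 0")
#' @export
extract_notes_annotations <- function(notes_text, dialect = notes_dialect(),
                                      registry = read_registry(),
                                      keep_unmatched = FALSE) {
  lines <- unlist(strsplit(notes_text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  anns <- list(); warnings <- character(0)
  push <- function(a) anns[[length(anns) + 1L]] <<- a
  for (line in lines) {
    m <- regmatches(line, regexec("^([A-Za-z_][A-Za-z0-9_ ]*?)\\s*:\\s*(.*)$", line))[[1]]
    field <- NULL
    if (length(m) == 3) {
      key <- toupper(gsub(" ", "_", trimws(m[2])))
      if (key %in% names(dialect)) field <- dialect[[key]]
    }
    if (is.null(field)) {
      if (keep_unmatched) push(ann_note(line))
      next
    }
    value <- trimws(m[3])
    res <- tryCatch({
      if (field == "formula") push(ann_formula(parse_formula(value)))
      else if (field == "charge") {
        q <- suppressWarnings(as.integer(value))
        if (is.na(q)) stop("non-integer charge: ", value, call. = FALSE)
        push(ann_charge(q))
      }
      else if (field == "inchi") push(ann_structure("inchi", value))
      else if (field == "smiles") push(ann_structure("smiles", value))
      else if (field == "synonym") push(ann_synonym(value))
      else if (field == "note") push(ann_note(value))
      else if (startsWith(field, "xref:")) {
        ns <- sub("^xref:", "", field)
        x <- xref(ns, value, registry)  # validates + canonicalizes
        push(ann_crossref(x$namespace, x$identifier))
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res))
      warnings <- c(warnings, sprintf("notes line '%s' rejected: %s", line, res))
  }
  list(annotations = anns, warnings = warnings)
}

# Inverse direction: notes lines for the annotations a CV term cannot
# carry. Cross references are not included (they go to CV terms).
annotations_to_notes_lines <- function(anns) {
  lines <- character(0)
  for (a in anns) {
    line <- switch(a$kind,
      formula   = paste0("FORMULA: ", format_formula(a$formula)),
      charge    = paste0("CHARGE: ", a$charge),
      structure = paste0(toupper(a$notation), ": ", a$value),
      synonym   = paste0("SYNONYM: ", a$value),
      note      = a$value,
      NULL)
    if (!is.null(line)) lines <- c(lines, line)
  }
  lines
}
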