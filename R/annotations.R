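# Dynamic multi-valued annotation system.
#
# Every model entity (metabolite, reaction) carries an ordered multiset of
# annotations. Kinds: crossref, structure, formula, charge, synonym, note.
# Identical kind+value pairs are stored once (dedupe by canonical key);
# distinct annotations keep insertion order.

ANNOTATION_KINDS <- c("crossref", "structure", "formula", "charge", "synonym", "note")

new_annotation <- function(kind, payload) {
  stopifnot(kind %in% ANNOTATION_KINDS)
  structure(c(list(kind = kind), payload), class = "mm_annotation")
}

#' Annotation constructors
#'
#' Build annotations to attach to metabolites or reactions. Each constructor
#' validates its payload: cross references carry a `(namespace, identifier)`
#' pair, structure annotations carry exactly one line notation, formulas are
#' element-count vectors, charges are integers.
#'
#' @param namespace Registry namespace token, e.g. `"chebi"`.
#' @param identifier Identifier text, e.g. `"CHEBI:15422"`.
#' @param notation `"inchi"` or `"smiles"`.
#' @param value Line-notation string / synonym text / free-text note.
#' @param formula Element counts (named integer vector) or formula string.
#' @param charge Integer charge.
#' @return An object of class `mm_annotation`.
#' @name annotation
#' @examples
#' ann_crossref("chebi", "CHEBI:15422")
#' ann_formula("C10H12N5O13P3")
NULL

#' @rdname annotation
#' @export
ann_crossref <- function(namespace, identifier) {
  stopifnot(is.character(namespace), nzchar(namespace),
            is.character(identifier), nzchar(identifier))
  new_annotation("crossref", list(namespace = namespace, identifier = identifier))
}

#' @rdname annotation
#' @export
ann_structure <- function(notation, value) {
  if (!notation %in% c("inchi", "smiles"))
    stop("notation must be 'inchi' or 'smiles'", call. = FALSE)
  stopifnot(is.character(value), nzchar(value))
  new_annotation("structure", list(notation = notation, value = value))
}

#' @rdname annotation
#' @export
ann_formula <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  new_annotation("formula", list(formula = ec_clean(formula)))
}

#' @rdname annotation
#' @export
ann_charge <- function(charge) {
  if (!is.numeric(charge) || length(charge) != 1 || charge != round(charge))
    stop("charge must be a single integer", call. = FALSE)
  new_annotation("charge", list(charge = as.integer(charge)))
}

#' @rdname annotation
#' @export
ann_synonym <- function(value) {
  stopifnot(is.character(value), nzchar(value))
  new_annotation("synonym", list(value = value))
}

#' @rdname annotation
#' @export
ann_note <- function(value) {
  stopifnot(is.character(value))
  new_annotation("note", list(value = value))
}

# Canonical dedupe key: identical kind+value <=> identical key.
ann_key <- function(a) {
  switch(a$kind,
    crossref  = paste0("crossref|", a$namespace, "|", a$identifier),
    structure = paste0("structure|", a$notation, "|", a$value),
    formula   = paste0("formula|", format_formula(a$formula)),
    charge    = paste0("charge|", a$charge),
    synonym   = paste0("synonym|", a$value),
    note      = paste0("note|", a$value))
}

#' Add an annotation to a metabolite or reaction
#'
#' Stores the annotation unless an identical kind+value annotation is
#' already present (the multiset is deduplicated, so repeated addition is
#' idempotent). Order of distinct annotations is preserved. The returned
#' entity carries attribute `"added"`: `TRUE` if storage occurred.
#'
#' @param entity An `mm_metabolite` or `mm_reaction`.
#' @param ann An `mm_annotation`.
#' @return The entity, with attribute `added`.
#' @examples
#' m <- metabolite("atp", "ATP", "c")
#' m <- add_annotation(m, ann_crossref("chebi", "CHEBI:15422"))
#' attr(m, "added")
#' @export
add_annotation <- function(entity, ann) {
  if (!inherits(ann, "mm_annotation"))
    stop("not an annotation object", call. = FALSE)
  if (!inherits(entity, c("mm_metabolite", "mm_reaction")))
    stop("annotations attach to metabolites or reactions", call. = FALSE)
  key <- ann_key(ann)
  keys <- vapply(entity$annotations, ann_key, character(1))
  if (key %in% keys) {
    attr(entity, "added") <- FALSE
    return(entity)
  }
  entity$annotations[[length(entity$annotations) + 1L]] <- ann
  attr(entity, "added") <- TRUE
  entity
}

#' Retrieve annotations of an entity, optionally filtered by kind
#'
#' @param entity An `mm_metabolite` or `mm_reaction`.
#' @param kind Optional kind filter (`"crossref"`, `"structure"`, ...).
#' @return List of `mm_annotation` objects in insertion order.
#' @export
annotations <- function(entity, kind = NULL) {
  anns <- entity$annotations
  if (!is.null(kind)) anns <- Filter(function(a) a$kind == kind, anns)
  anns
}

# sorted multiset of keys, used for order-insensitive equality
ann_multiset <- function(entity) sort(vapply(entity$annotations, ann_key, character(1)))

has_structure <- function(entity) length(annotations(entity, "structure")) > 0

# Formula precedence: explicit formula annotation > structure-derived.
# Returns list(formula=..., source=...) or NULL.
entity_formula <- function(entity) {
  f <- annotations(entity, "formula")
  if (length(f) > 0) return(list(formula = f[[1]]$formula, source = "annotation"))
  for (s in annotations(entity, "structure")) {
    if (s$notation == "inchi") {
      derived <- inchi_formula(s$value)
      if (!is.null(derived)) return(list(formula = derived, source = "structure"))
    }
  }
  NULL
}

entity_charge <- function(entity) {
  q <- annotations(entity, "charge")
  if (length(q) > 0) return(q[[1]]$charge)
  for (s in annotations(entity, "structure")) {
    if (s$notation == "inchi") {
      derived <- inchi_charge(s$value)
      if (!is.null(derived)) return(derived)
    }
  }
  NULL
}

#' @export
print.mm_annotation <- function(x, ...) {
  cat("<annotation>", ann_key(x), "\n")
  invisible(x)
}
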