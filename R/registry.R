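# MIRIAM registry snapshot: namespace -> identifier pattern + URI base.
#
# The registry is a bundled, versioned JSON snapshot (no live web fetch), so
# identifier-resource inference and URI encoding are reproducible offline.
# Users can substitute their own snapshot with the same schema.

#' Load a MIRIAM registry snapshot
#'
#' Reads a registry snapshot: a JSON document with fields `format`,
#' `version` and `entries`, each entry carrying `namespace`, `display_name`,
#' `pattern` (anchored regular expression for valid identifiers),
#' `uri_base` (identifiers.org prefix ending in `/`), optional `id_prefix`
#' (literal identifier prefix such as `"CHEBI:"`) and optional `aliases`
#' (legacy namespace tokens such as `"obo.chebi"`). With no argument the
#' snapshot bundled with the package is loaded.
#'
#' @param path Path to a registry JSON file, or `NULL` for the bundled one.
#' @return Object of class `mm_registry`.
#' @examples
#' reg <- read_registry()
#' reg$version
#' @export
read_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "miriam_registry.json", package = "metanno")
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$entries) || length(raw$entries) == 0)
    stop("registry snapshot has no entries", call. = FALSE)
  entries <- lapply(raw$entries, function(e) {
    stopifnot(!is.null(e$namespace), !is.null(e$pattern), !is.null(e$uri_base))
    if (!grepl("/$", e$uri_base))
      stop("uri_base must end with '/': ", e$namespace, call. = FALSE)
    if (!grepl("^\\^", e$pattern) || !grepl("\\$$", e$pattern))
      stop("pattern must be anchored (^...$): ", e$namespace, call. = FALSE)
    list(namespace = e$namespace,
         display_name = if (is.null(e$display_name)) e$namespace else e$display_name,
         pattern = e$pattern,
         uri_base = e$uri_base,
         id_prefix = e$id_prefix,
         aliases = as.character(unlist(e$aliases)))
  })
  names(entries) <- vapply(entries, `[[`, character(1), "namespace")
  alias_map <- list()
  for (e in entries) for (a in e$aliases) alias_map[[a]] <- e$namespace
  structure(list(entries = entries, alias_map = alias_map,
                 version = if (is.null(raw$version)) "unversioned" else raw$version),
            class = "mm_registry")
}

registry_entry <- function(registry, namespace) {
  ns <- namespace
  if (!ns %in% names(registry$entries) && ns %in% names(registry$alias_map))
    ns <- registry$alias_map[[ns]]
  if (!ns %in% names(registry$entries))
    stop("unknown namespace: ", namespace, call. = FALSE)
  registry$entries[[ns]]
}

# anchored full match; patterns may contain alternations, so wrap
pattern_match <- function(pattern, x) {
  grepl(paste0("^(", sub("\\$$", "", sub("^\\^", "", pattern)), ")$"), x, perl = TRUE)
}

# Canonical identifier for a namespace: inserts the literal id prefix when
# the namespace requires one and the bare form was given.
canonical_identifier <- function(identifier, entry) {
  if (pattern_match(entry$pattern, identifier)) return(identifier)
  if (!is.null(entry$id_prefix)) {
    cand <- paste0(entry$id_prefix, identifier)
    if (pattern_match(entry$pattern, cand)) return(cand)
  }
  NULL
}

#' Create a validated cross reference
#'
#' @param namespace Registry namespace token (aliases resolved).
#' @param identifier Identifier text; a missing literal prefix (e.g. bare
#'   `"15422"` for ChEBI) is inserted during canonicalization.
#' @param registry An `mm_registry`.
#' @return Object of class `mm_xref` with fields `namespace`, `identifier`.
#' @examples
#' xref("chebi", "CHEBI:15422", read_registry())
#' @export
xref <- function(namespace, identifier, registry) {
  entry <- registry_entry(registry, namespace)
  canon <- canonical_identifier(identifier, entry)
  if (is.null(canon))
    stop(sprintf("identifier '%s' does not match pattern for namespace '%s' (%s)",
                 identifier, entry$namespace, entry$pattern), call. = FALSE)
  structure(list(namespace = entry$namespace, identifier = canon),
            class = "mm_xref")
}

#' Infer which resources a bare identifier belongs to
#'
#' Matches the identifier against every namespace pattern in the registry.
#' Candidates whose literal identifier prefix (e.g. `"CHEBI:"`) matches the
#' input are ranked first; remaining matches follow in registry order. An
#' empty result means no namespace recognizes the identifier; more than one
#' candidate means the caller must disambiguate.
#'
#' @param identifier Identifier text, e.g. `"CHEBI:15422"` or `"C00002"`.
#' @param registry An `mm_registry`.
#' @return Character vector of candidate namespaces (possibly empty).
#' @examples
#' infer_resource("CHEBI:15422", read_registry())
#' infer_resource("C00002", read_registry())
#' @export
infer_resource <- function(identifier, registry) {
  stopifnot(is.character(identifier), nzchar(identifier))
  hits <- character(0); prefixed <- logical(0)
  for (e in registry$entries) {
    if (pattern_match(e$pattern, identifier)) {
      hits <- c(hits, e$namespace)
      prefixed <- c(prefixed,
                    !is.null(e$id_prefix) && startsWith(identifier, e$id_prefix))
    }
  }
  c(hits[prefixed], hits[!prefixed])
}

#' Encode a cross reference as an identifiers.org URI
#'
#' @param x An `mm_xref` (or a list with `namespace` and `identifier`).
#' @param registry An `mm_registry`.
#' @return URI string, e.g. `"https://identifiers.org/chebi/CHEBI:15422"`.
#' @examples
#' to_uri(xref("chebi", "CHEBI:15422", read_registry()), read_registry())
#' @export
to_uri <- function(x, registry) {
  entry <- registry_entry(registry, x$namespace)
  canon <- canonical_identifier(x$identifier, entry)
  if (is.null(canon))
    stop(sprintf("identifier '%s' invalid for namespace '%s'",
                 x$identifier, entry$namespace), call. = FALSE)
  paste0(entry$uri_base, canon)
}

#' Decode an identifiers.org URI or legacy MIRIAM URN
#'
#' Inverse of [to_uri()] on its range. Accepts `https://identifiers.org/...`
#' and `http://identifiers.org/...` forms as well as the legacy
#' `urn:miriam:namespace:identifier` form with percent-encoded characters
#' (`CHEBI%3A15422`); legacy namespace aliases (`obo.chebi`) are resolved
#' through the snapshot's alias table.
#'
#' @param uri URI text.
#' @param registry An `mm_registry`.
#' @return An `mm_xref`.
#' @examples
#' from_uri("https://identifiers.org/chebi/CHEBI:15422", read_registry())
#' from_uri("urn:miriam:obo.chebi:CHEBI%3A15422", read_registry())
#' @export
from_uri <- function(uri, registry) {
  stopifnot(is.character(uri), length(uri) == 1)
  if (grepl("^urn:miriam:", uri)) {
    rest <- sub("^urn:miriam:", "", uri)
    i <- regexpr(":", rest, fixed = TRUE)
    if (i < 0) stop("malformed MIRIAM URN: ", uri, call. = FALSE)
    ns <- substr(rest, 1, i - 1)
    id <- utils::URLdecode(substr(rest, i + 1, nchar(rest)))
    return(xref(ns, id, registry))
  }
  m <- regmatches(uri, regexec("^https?://identifiers\\.org/([^/]+)/(.+)$", uri))[[1]]
  if (length(m) == 3) return(xref(m[2], utils::URLdecode(m[3]), registry))
  stop("unrecognized cross-reference URI: ", uri, call. = FALSE)
}

#' @export
print.mm_registry <- function(x, ...) {
  cat(sprintf("<MIRIAM registry snapshot %s: %d namespaces>\n",
              x$version, length(x$entries)))
  invisible(x)
}

#' @export
print.mm_xref <- function(x, ...) {
  cat(sprintf("<xref> %s:%s\n", x$namespace, x$identifier))
  invisible(x)
}
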