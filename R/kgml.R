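# Minimal KGML (KEGG pathway XML) import: compound entries and reactions.
# Map/graphics elements are ignored; only model content is read.

#' Read a minimal KGML pathway file
#'
#' Compound `entry` elements become metabolites named by the KGML `name`
#' attribute, with the `cpd:`-stripped token stored as a validated
#' `kegg.compound` cross reference. `reaction` elements become reactions
#' with all substrates and products at coefficient 1; the `type` attribute
#' (`reversible`/`irreversible`) sets reversibility. A pathway without
#' reactions yields a metabolites-only model with a warning.
#'
#' @param path KGML file path.
#' @param registry An `mm_registry`.
#' @return An `mm_model`.
#' @export
read_kgml <- function(path, registry = read_registry()) {
  doc <- xml2::read_xml(path)
  m <- model(
    { nm <- xml2::xml_attr(doc, "name"); if (is.na(nm)) "kgml" else nm },
    c(c = "cytosol"))

  # entry id -> metabolite id (KGML reactions reference entry names)
  for (entry in xml2::xml_find_all(doc, "//entry[@type='compound']")) {
    kegg_name <- xml2::xml_attr(entry, "name")  # e.g. "cpd:C00002"
    token <- sub("^cpd:", "", kegg_name)
    if (token %in% names(m$metabolites)) next
    met <- metabolite(token, token, "c")
    x <- tryCatch(xref("kegg.compound", token, registry), error = function(e) NULL)
    if (!is.null(x)) {
      met <- add_annotation(met, ann_crossref(x$namespace, x$identifier))
    } else {
      warning("entry '", kegg_name, "' is not a valid kegg.compound id",
              call. = FALSE)
    }
    attr(met, "added") <- NULL
    m <- model_add_metabolite(m, met)
  }

  rx_nodes <- xml2::xml_find_all(doc, "//reaction")
  if (length(rx_nodes) == 0)
    warning("KGML file has no reactions; model contains metabolites only",
            call. = FALSE)
  for (rx in rx_nodes) {
    rid <- sub("^rn:", "", xml2::xml_attr(rx, "name"))
    if (is.na(rid) || !nzchar(rid)) rid <- paste0("kgml_r", length(m$reactions) + 1)
    reversible <- identical(xml2::xml_attr(rx, "type"), "reversible")
    side_tokens <- function(tag) {
      nodes <- xml2::xml_find_all(rx, sprintf("./%s", tag))
      sub("^cpd:", "", vapply(nodes, xml2::xml_attr, character(1), "name"))
    }
    subs <- side_tokens("substrate"); prods <- side_tokens("product")
    all_tok <- c(subs, prods)
    for (tok in setdiff(all_tok, names(m$metabolites)))
      m <- model_add_metabolite(m, metabolite(tok, tok, "c"))
    parts <- new_participants(
      c(subs, prods), rep(1, length(all_tok)), rep(1, length(all_tok)),
      c(rep("reactant", length(subs)), rep("product", length(prods))))
    rxn <- structure(list(id = rid, name = rid, participants = parts,
                          reversible = reversible, annotations = list()),
                     class = "mm_reaction")
    kx <- tryCatch(xref("kegg.reaction", rid, registry), error = function(e) NULL)
    if (!is.null(kx)) rxn <- add_annotation(rxn, ann_crossref(kx$namespace, kx$identifier))
    attr(rxn, "added") <- NULL
    m <- model_add_reaction(m, rxn)
  }
  m
}
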