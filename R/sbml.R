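# SBML interchange.
#
# Reader accepts SBML Level 2 and Level 3 core; writer emits Level 3
# Version 1 core. Cross references travel as RDF CV terms (biology
# qualifier "is") with identifiers.org URIs; formula, charge, line
# notations and synonyms travel as structured notes lines; CV-term URIs the
# registry cannot resolve are preserved as note annotations rather than
# dropped. Implemented directly on xml2 (namespace-agnostic XPath on read).

SBML_L3_NS <- "http://www.sbml.org/sbml/level3/version1/core"
XHTML_NS <- "http://www.w3.org/1999/xhtml"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
BQBIOL_NS <- "http://biomodels.net/biology-qualifiers/"

xfind <- function(node, local) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", local))
}

node_notes_lines <- function(node) {
  notes <- xml2::xml_find_first(node, "./*[local-name()='notes']")
  if (inherits(notes, "xml_missing")) return(character(0))
  ps <- xml2::xml_find_all(notes, ".//*[local-name()='p']")
  if (length(ps) > 0) {
    lines <- xml2::xml_text(ps)
  } else {
    lines <- unlist(strsplit(xml2::xml_text(notes), "\n", fixed = TRUE))
  }
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

node_cvterm_uris <- function(node) {
  ann <- xml2::xml_find_first(node, "./*[local-name()='annotation']")
  if (inherits(ann, "xml_missing")) return(character(0))
  lis <- xml2::xml_find_all(ann, ".//*[local-name()='li']")
  uris <- vapply(lis, function(li) {
    attrs <- xml2::xml_attrs(li)
    hit <- grep("resource$", names(attrs), value = TRUE)
    if (length(hit) == 0) NA_character_ else attrs[[hit[1]]]
  }, character(1))
  uris[!is.na(uris)]
}

# fold CV URIs + notes lines into entity annotations
apply_node_annotations <- function(entity, node, dialect, registry, extract_notes) {
  for (uri in node_cvterm_uris(node)) {
    x <- tryCatch(from_uri(uri, registry), error = function(e) NULL)
    entity <- if (is.null(x)) {
      add_annotation(entity, ann_note(uri))  # unresolvable: keep, never drop
    } else {
      add_annotation(entity, ann_crossref(x$namespace, x$identifier))
    }
  }
  lines <- node_notes_lines(node)
  if (length(lines) > 0) {
    if (extract_notes) {
      res <- extract_notes_annotations(paste(lines, collapse = "\n"),
                                       dialect, registry, keep_unmatched = TRUE)
      for (w in res$warnings) warning(w, call. = FALSE)
      for (a in res$annotations) entity <- add_annotation(entity, a)
    } else {
      for (line in lines) entity <- add_annotation(entity, ann_note(line))
    }
  }
  attr(entity, "added") <- NULL
  entity
}

#' Read an SBML model
#'
#' Parses SBML Level 2 or Level 3 (core). Species become metabolites with
#' compartment, name and any charge attribute (L2); reactions keep exact
#' stoichiometry and reversibility. CV-term resource URIs are decoded to
#' cross references via [from_uri()]; URIs the registry cannot resolve are
#' kept as note annotations. Notes lines matching the dialect become typed
#' annotations when `extract_notes = TRUE` (default); with
#' `extract_notes = FALSE` every notes line is kept verbatim as a `note`
#' annotation (raw mode, used ahead of [transfer_structures()]).
#'
#' @param path SBML file path.
#' @param registry An `mm_registry`.
#' @param dialect Notes alias table, see [notes_dialect()].
#' @param extract_notes Type recognized notes lines into annotations?
#' @return An `mm_model`.
#' @export
read_sbml <- function(path, registry = read_registry(),
                      dialect = notes_dialect(), extract_notes = TRUE) {
  doc <- xml2::read_xml(path)  # malformed XML errors here with line info
  model_node <- xml2::xml_find_first(doc, "/*/*[local-name()='model']")
  if (inherits(model_node, "xml_missing"))
    stop("no <model> element in ", path, call. = FALSE)

  comp_nodes <- xfind(model_node, "compartment")
  compartments <- stats::setNames(
    vapply(comp_nodes, function(n) {
      nm <- xml2::xml_attr(n, "name")
      if (is.na(nm)) xml2::xml_attr(n, "id") else nm
    }, character(1)),
    vapply(comp_nodes, xml2::xml_attr, character(1), "id"))
  if (length(compartments) == 0) compartments <- c(c = "cytosol")

  mid <- xml2::xml_attr(model_node, "id")
  m <- model(if (is.na(mid)) "model" else mid, compartments)

  for (sp in xfind(model_node, "species")) {
    id <- xml2::xml_attr(sp, "id")
    nm <- xml2::xml_attr(sp, "name")
    comp <- xml2::xml_attr(sp, "compartment")
    met <- metabolite(id, if (is.na(nm)) id else nm,
                      if (is.na(comp)) "c" else comp)
    q <- xml2::xml_attr(sp, "charge")  # SBML L2 species attribute
    if (!is.na(q)) met <- add_annotation(met, ann_charge(as.integer(q)))
    met <- apply_node_annotations(met, sp, dialect, registry, extract_notes)
    m <- model_add_metabolite(m, met)
  }

  for (rx in xfind(model_node, "reaction")) {
    id <- xml2::xml_attr(rx, "id")
    nm <- xml2::xml_attr(rx, "name")
    rev_attr <- xml2::xml_attr(rx, "reversible")
    reversible <- is.na(rev_attr) || identical(rev_attr, "true")
    side_refs <- function(list_name, side) {
      lst <- xml2::xml_find_first(rx, sprintf("./*[local-name()='%s']", list_name))
      if (inherits(lst, "xml_missing")) return(NULL)
      refs <- xml2::xml_find_all(lst, "./*[local-name()='speciesReference']")
      do.call(rbind, lapply(refs, function(ref) {
        sp_id <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        r <- if (is.na(st)) list(num = 1, den = 1) else rat_parse(st)
        if (is.null(r))
          stop("unparseable stoichiometry '", st, "' in reaction ", id, call. = FALSE)
        new_participants(sp_id, r$num, r$den, side)
      }))
    }
    parts <- rbind(side_refs("listOfReactants", "reactant"),
                   side_refs("listOfProducts", "product"))
    if (is.null(parts) || nrow(parts) == 0)
      stop("reaction ", id, " has no participants", call. = FALSE)
    rxn <- structure(list(id = id, name = if (is.na(nm)) id else nm,
                          participants = parts, reversible = reversible,
                          annotations = list()),
                     class = "mm_reaction")
    rxn <- apply_node_annotations(rxn, rx, dialect, registry, extract_notes)
    m <- model_add_reaction(m, rxn)  # dangling references error here
  }
  m
}

sbml_entity_children <- function(node, entity, registry) {
  lines <- annotations_to_notes_lines(entity$annotations)
  if (length(lines) > 0) {
    notes <- xml2::xml_add_child(node, "notes")
    body <- xml2::xml_add_child(notes, "body", xmlns = XHTML_NS)
    for (line in lines) xml2::xml_add_child(body, "p", line)
  }
  xrefs <- annotations(entity, "crossref")
  if (length(xrefs) > 0) {
    bad <- character(0)
    uris <- vapply(xrefs, function(a) {
      tryCatch(to_uri(list(namespace = a$namespace, identifier = a$identifier),
                      registry),
               error = function(e) { bad <<- c(bad, entity$id); NA_character_ })
    }, character(1))
    if (length(bad) > 0)
      stop("cross references failing registry validation on: ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    ann <- xml2::xml_add_child(node, "annotation")
    rdf <- xml2::xml_add_child(ann, "rdf:RDF")
    desc <- xml2::xml_add_child(rdf, "rdf:Description",
                                "rdf:about" = paste0("#meta_", entity$id))
    is_q <- xml2::xml_add_child(desc, "bqbiol:is")
    bag <- xml2::xml_add_child(is_q, "rdf:Bag")
    for (uri in uris)
      xml2::xml_add_child(bag, "rdf:li", "rdf:resource" = uri)
  }
  invisible(node)
}

#' Write a model as SBML Level 3 Version 1
#'
#' Every cross-reference annotation becomes an RDF CV term (biology
#' qualifier `is`) with an identifiers.org URI; structure annotations
#' (InChI/SMILES), formulas, charges, synonyms and notes are written as
#' structured notes lines under the default dialect keys. Cross references
#' that fail registry validation abort the write with the offending entity
#' ids. `read_sbml(write_sbml(m))` preserves the model up to annotation
#' ordering.
#'
#' @param model An `mm_model`.
#' @param path Output file path.
#' @param registry An `mm_registry`.
#' @return Invisibly, the output path.
#' @export
write_sbml <- function(model, path, registry = read_registry()) {
  for (rxn in model$reactions) {
    missing <- setdiff(rxn$participants$metabolite, names(model$metabolites))
    if (length(missing) > 0)
      stop("reaction ", rxn$id, " references unknown metabolites: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_L3_NS,
                            "xmlns:rdf" = RDF_NS, "xmlns:bqbiol" = BQBIOL_NS,
                            level = "3", version = "1")
  mnode <- xml2::xml_add_child(doc, "model", id = model$id)
  xml2::xml_add_child(
    mnode,
    xml2::xml_comment(sprintf(" annotated with metanno; registry snapshot %s ",
                              registry$version)))

  comps <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (tok in names(model$compartments))
    xml2::xml_add_child(comps, "compartment", id = tok,
                        name = model$compartments[[tok]], constant = "true")

  if (length(model$metabolites) > 0) {
    sps <- xml2::xml_add_child(mnode, "listOfSpecies")
    for (met in model$metabolites) {
      sp <- xml2::xml_add_child(sps, "species", id = met$id,
                                metaid = paste0("meta_", met$id),
                                name = met$name, compartment = met$compartment,
                                hasOnlySubstanceUnits = "false",
                                boundaryCondition = "false", constant = "false")
      sbml_entity_children(sp, met, registry)
    }
  }

  if (length(model$reactions) > 0) {
    rxs <- xml2::xml_add_child(mnode, "listOfReactions")
    for (rxn in model$reactions) {
      rx <- xml2::xml_add_child(rxs, "reaction", id = rxn$id,
                                metaid = paste0("meta_", rxn$id),
                                name = rxn$name,
                                reversible = if (rxn$reversible) "true" else "false",
                                fast = "false")
      sbml_entity_children(rx, rxn, registry)
      for (side in c("reactant", "product")) {
        df <- rxn$participants[rxn$participants$side == side, , drop = FALSE]
        if (nrow(df) == 0) next
        lst <- xml2::xml_add_child(
          rx, if (side == "reactant") "listOfReactants" else "listOfProducts")
        for (i in seq_len(nrow(df))) {
          st <- if (rat_is_decimal(df$den[i])) {
            rat_format(df$num[i], df$den[i])
          } else {
            format(df$num[i] / df$den[i], digits = 17)
          }
          xml2::xml_add_child(lst, "speciesReference", species = df$metabolite[i],
                              stoichiometry = st, constant = "true")
        }
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
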