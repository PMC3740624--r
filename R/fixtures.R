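# Deterministic toy-model fixture generator.
#
# Emulates, at desk scale and fully offline, the inputs the annotation
# pipeline consumes: an SBML model, matching spreadsheet tables, a minimal
# KGML snippet, per-resource chemical tables, a registry snapshot and the
# residue table. Chemistry is drawn from a hardcoded vocabulary of real
# metabolites with literature-standard formulas and anion-convention
# charges, so balance checks run against genuine stoichiometry. Defects
# (one imbalanced reaction, structure-less and ambiguously named
# metabolites) are injected under flags and listed in a manifest.

FIXTURE_VOCAB <- list(
  atp    = list(name = "ATP", formula = "C10H12N5O13P3", charge = -4L,
                chebi = "CHEBI:30616", kegg = "C00002",
                smiles = "Nc1ncnc2n(cnc12)C1OC(COP(=O)([O-])OP(=O)([O-])OP(=O)([O-])[O-])C(O)C1O"),
  adp    = list(name = "ADP", formula = "C10H12N5O10P2", charge = -3L,
                chebi = "CHEBI:456216", kegg = "C00008",
                smiles = "Nc1ncnc2n(cnc12)C1OC(COP(=O)([O-])OP(=O)([O-])[O-])C(O)C1O"),
  pi     = list(name = "phosphate", formula = "HO4P", charge = -2L,
                chebi = "CHEBI:43474", kegg = "C00009",
                smiles = "OP(=O)([O-])[O-]"),
  h      = list(name = "H+", formula = "H", charge = 1L,
                chebi = "CHEBI:15378", kegg = "C00080", smiles = "[H+]"),
  h2o    = list(name = "H2O", formula = "H2O", charge = 0L,
                chebi = "CHEBI:15377", kegg = "C00001", smiles = "O",
                inchi = "InChI=1S/H2O/h1H2"),
  glc    = list(name = "D-Glucose", formula = "C6H12O6", charge = 0L,
                chebi = "CHEBI:4167", kegg = "C00031",
                smiles = "OCC1OC(O)C(O)C(O)C1O",
                synonyms = "grape sugar|dextrose"),
  g6p    = list(name = "D-Glucose 6-phosphate", formula = "C6H11O9P", charge = -2L,
                chebi = "CHEBI:61548", kegg = "C00092",
                smiles = "OC1OC(COP(=O)([O-])[O-])C(O)C(O)C1O"),
  gly    = list(name = "glycine", formula = "C2H5NO2", charge = 0L,
                chebi = "CHEBI:15428", kegg = "C00037", smiles = "NCC(O)=O",
                inchi = "InChI=1S/C2H5NO2/c3-1-2(4)5/h1,3H2,(H,4,5)"),
  ala    = list(name = "L-alanine", formula = "C3H7NO2", charge = 0L,
                chebi = "CHEBI:16977", kegg = "C00041", smiles = "CC(N)C(O)=O"),
  glygly = list(name = "glycylglycine", formula = "C4H8N2O3", charge = 0L,
                chebi = "CHEBI:17201", kegg = "C02037", smiles = NULL),
  pyr    = list(name = "pyruvate", formula = "C3H3O3", charge = -1L,
                chebi = "CHEBI:15361", kegg = "C00022", smiles = "CC(=O)C([O-])=O"),
  lac    = list(name = "(S)-lactate", formula = "C3H5O3", charge = -1L,
                chebi = "CHEBI:16651", kegg = "C00186", smiles = "CC(O)C([O-])=O"),
  o2     = list(name = "O2", formula = "O2", charge = 0L,
                chebi = "CHEBI:15379", kegg = "C00007", smiles = "O=O"),
  co2    = list(name = "CO2", formula = "CO2", charge = 0L,
                chebi = "CHEBI:16526", kegg = "C00011", smiles = "O=C=O")
)

FIXTURE_REACTIONS <- list(
  R_atph = list(reactants = c(atp = 1, h2o = 1),
                products = c(adp = 1, pi = 1, h = 1),
                reversible = FALSE, name = "ATP hydrolysis"),
  R_hex  = list(reactants = c(glc = 1, atp = 1),
                products = c(g6p = 1, adp = 1, h = 1),
                reversible = FALSE, name = "hexokinase"),
  R_pep  = list(reactants = c(gly = 2),
                products = c(glygly = 1, h2o = 1),
                reversible = FALSE, name = "glycylglycine synthesis"),
  R_ox   = list(reactants = c(glc = 1, o2 = 6),
                products = c(co2 = 6, h2o = 6),
                reversible = FALSE, name = "glucose oxidation"),
  R_ex_glc = list(reactants = c(), products = c(glc = 1),
                  reversible = TRUE, name = "glucose exchange")
)

#' Specify a fixture bundle
#'
#' @param seed Integer RNG seed; the same seed yields a byte-identical
#'   bundle.
#' @param n_metabolites Minimum number of metabolites (reaction
#'   participants are always included, then unused vocabulary pads up to
#'   this count; the vocabulary holds 14 metabolites).
#' @param n_reactions Number of reactions drawn from the fixed pool.
#' @param fraction_annotated Fraction of metabolites receiving cross
#'   references and structure annotations; formula and charge are always
#'   present so balance status stays determined.
#' @param include_imbalanced Inject one mass/charge-imbalanced reaction
#'   (ATP hydrolysis with the proton omitted)?
#' @param include_peptides Include a structure-less metabolite named
#'   "glycylglycine", annotatable by peptide assembly?
#' @param include_ambiguous Inject a pair of metabolites whose names
#'   normalize identically?
#' @return List of class `mm_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_metabolites = 14L, n_reactions = 5L,
                         fraction_annotated = 0.6,
                         include_imbalanced = TRUE,
                         include_peptides = TRUE,
                         include_ambiguous = TRUE) {
  stopifnot(n_metabolites >= 1, n_reactions >= 1,
            fraction_annotated >= 0, fraction_annotated <= 1)
  structure(list(seed = as.integer(seed), n_metabolites = as.integer(n_metabolites),
                 n_reactions = as.integer(n_reactions),
                 fraction_annotated = fraction_annotated,
                 include_imbalanced = isTRUE(include_imbalanced),
                 include_peptides = isTRUE(include_peptides),
                 include_ambiguous = isTRUE(include_ambiguous)),
            class = "mm_fixture_spec")
}

with_fixture_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Generate a fixture bundle
#'
#' Writes into `dir`: `model.sbml`, `metabolites.tsv` + `reactions.tsv` +
#' `mapping.json` (spreadsheet form of the same model), `pathway.kgml`,
#' `chebi.tsv` + `kegg.tsv` resource tables with `index_config.json`,
#' copies of the registry snapshot and residue table, and `manifest.json`
#' listing every injected defect. The generated model is internally
#' consistent except for the deliberate defects.
#'
#' @param spec An [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
generate_fixtures <- function(spec = fixture_spec(), dir) {
  stopifnot(inherits(spec, "mm_fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  pool <- FIXTURE_REACTIONS
  if (!spec$include_peptides) pool$R_pep <- NULL
  n_bal <- spec$n_reactions - as.integer(spec$include_imbalanced)
  n_bal <- max(1L, min(n_bal, length(pool)))

  with_fixture_rng(spec$seed, {
    chosen <- sort(names(pool)[sample.int(length(pool), n_bal)])
    rxns <- pool[chosen]
    if (spec$include_imbalanced)
      rxns$R_atph_bad <- list(reactants = c(atp = 1, h2o = 1),
                              products = c(adp = 1, pi = 1),
                              reversible = FALSE,
                              name = "ATP hydrolysis (proton missing)")

    needed <- unique(unlist(lapply(rxns, function(r)
      c(names(r$reactants), names(r$products)))))
    if (spec$include_peptides) needed <- unique(c(needed, "glygly"))
    spare <- setdiff(names(FIXTURE_VOCAB), needed)
    pad <- setdiff(spare, character(0))
    extra <- max(0L, spec$n_metabolites - length(needed))
    if (extra > 0 && length(pad) > 0)
      needed <- c(needed,
                  sort(pad[sample.int(length(pad), min(extra, length(pad)))]))
    met_ids <- sort(needed)

    # metabolites never annotated with xref/structure: the peptide
    # showcase and the ambiguous twin
    protected <- character(0)
    if (spec$include_peptides) protected <- c(protected, "glygly")
    annotatable <- setdiff(met_ids, protected)
    n_ann <- round(spec$fraction_annotated * length(annotatable))
    annotated <- if (n_ann > 0)
      sort(annotatable[sample.int(length(annotatable), n_ann)]) else character(0)

    m <- model("fixture_model", c(c = "cytosol"))
    for (id in met_ids) {
      v <- FIXTURE_VOCAB[[id]]
      met <- metabolite(id, v$name, "c")
      met <- add_annotation(met, ann_formula(v$formula))
      met <- add_annotation(met, ann_charge(v$charge))
      if (id %in% annotated) {
        met <- add_annotation(met, ann_crossref("chebi", v$chebi))
        met <- add_annotation(met, ann_crossref("kegg.compound", v$kegg))
        if (!is.null(v$inchi)) met <- add_annotation(met, ann_structure("inchi", v$inchi))
        if (!is.null(v$smiles)) met <- add_annotation(met, ann_structure("smiles", v$smiles))
      }
      attr(met, "added") <- NULL
      m <- model_add_metabolite(m, met)
    }
    if (spec$include_ambiguous) {
      twin <- metabolite("glc_dup", "D glucose", "c")
      twin <- add_annotation(twin, ann_formula("C6H12O6"))
      twin <- add_annotation(twin, ann_charge(0L))
      attr(twin, "added") <- NULL
      if (!"glc" %in% met_ids)
        m <- model_add_metabolite(m, {
          v <- FIXTURE_VOCAB$glc
          g <- metabolite("glc", v$name, "c")
          g <- add_annotation(g, ann_formula(v$formula))
          g <- add_annotation(g, ann_charge(v$charge))
          attr(g, "added") <- NULL
          g
        })
      m <- model_add_metabolite(m, twin)
    }
    for (rid in names(rxns)) {
      r <- rxns[[rid]]
      m <- model_add_reaction(m, reaction(rid, r$reactants, r$products,
                                          r$reversible, r$name))
    }

    registry <- read_registry()
    write_sbml(m, file.path(dir, "model.sbml"), registry)

    # spreadsheet form of the same model graph
    all_ids <- names(m$metabolites)
    met_df <- data.frame(
      id = all_ids,
      name = vapply(all_ids, function(i) m$metabolites[[i]]$name, character(1)),
      formula = vapply(all_ids, function(i) {
        f <- entity_formula(m$metabolites[[i]]); format_formula(f$formula)
      }, character(1)),
      charge = vapply(all_ids, function(i) entity_charge(m$metabolites[[i]]),
                      integer(1)),
      compartment = "c",
      chebi = vapply(all_ids, function(i) {
        xs <- annotations(m$metabolites[[i]], "crossref")
        xs <- Filter(function(a) a$namespace == "chebi", xs)
        if (length(xs) == 0) "" else xs[[1]]$identifier
      }, character(1)),
      stringsAsFactors = FALSE)
    write_tsv(met_df, file.path(dir, "metabolites.tsv"))
    rxn_df <- data.frame(
      id = names(m$reactions),
      equation = vapply(m$reactions, function(r) {
        parts <- r$participants
        parts$name <- parts$metabolite
        parts$compartment <- "c"
        fmt_participants(parts, r$reversible)
      }, character(1)),
      stringsAsFactors = FALSE)
    write_tsv(rxn_df, file.path(dir, "reactions.tsv"))
    writeLines(jsonlite::toJSON(list(
      metabolites = list(id = "id", name = "name", formula = "formula",
                         charge = "charge", compartment = "compartment",
                         "xref:chebi" = "chebi"),
      reactions = list(id = "id", equation = "equation")),
      auto_unbox = TRUE), file.path(dir, "mapping.json"))

    # minimal KGML snippet (static content, model-independent)
    kgml <- xml2::xml_new_root("pathway", name = "path:toy00001",
                               org = "toy", number = "00001")
    ids <- c(C00002 = "1", C00001 = "2", C00008 = "3", C00009 = "4")
    for (k in names(ids))
      xml2::xml_add_child(kgml, "entry", id = ids[[k]],
                          name = paste0("cpd:", k), type = "compound")
    rx <- xml2::xml_add_child(kgml, "reaction", id = "5", name = "rn:R00086",
                              type = "reversible")
    xml2::xml_add_child(rx, "substrate", id = "1", name = "cpd:C00002")
    xml2::xml_add_child(rx, "substrate", id = "2", name = "cpd:C00001")
    xml2::xml_add_child(rx, "product", id = "3", name = "cpd:C00008")
    xml2::xml_add_child(rx, "product", id = "4", name = "cpd:C00009")
    xml2::write_xml(kgml, file.path(dir, "pathway.kgml"))

    # resource tables: every vocabulary compound except the peptide
    # showcase, so name/xref lookups always resolve to a structure
    tbl_ids <- setdiff(names(FIXTURE_VOCAB), "glygly")
    res_df <- function(ns_field) {
      data.frame(
        identifier = vapply(tbl_ids, function(i) FIXTURE_VOCAB[[i]][[ns_field]],
                            character(1)),
        name = vapply(tbl_ids, function(i) FIXTURE_VOCAB[[i]]$name, character(1)),
        synonyms = vapply(tbl_ids, function(i)
          FIXTURE_VOCAB[[i]]$synonyms %||% "", character(1)),
        formula = vapply(tbl_ids, function(i) FIXTURE_VOCAB[[i]]$formula,
                         character(1)),
        charge = vapply(tbl_ids, function(i) FIXTURE_VOCAB[[i]]$charge, integer(1)),
        inchi = vapply(tbl_ids, function(i) FIXTURE_VOCAB[[i]]$inchi %||% "",
                       character(1)),
        smiles = vapply(tbl_ids, function(i) FIXTURE_VOCAB[[i]]$smiles %||% "",
                        character(1)),
        stringsAsFactors = FALSE)
    }
    write_tsv(res_df("chebi"), file.path(dir, "chebi.tsv"))
    write_tsv(res_df("kegg"), file.path(dir, "kegg.tsv"))
    writeLines(jsonlite::toJSON(list(tables = list(list(
      namespace = "chebi", path = "chebi.tsv"))), auto_unbox = TRUE),
      file.path(dir, "index_config.json"))

    file.copy(system.file("extdata", "miriam_registry.json", package = "metanno"),
              file.path(dir, "registry.json"), overwrite = TRUE)
    file.copy(system.file("extdata", "residues.tsv", package = "metanno"),
              file.path(dir, "residues.tsv"), overwrite = TRUE)

    all_ids <- sort(names(m$metabolites))
    manifest <- list(
      seed = spec$seed,
      n_metabolites = length(m$metabolites),
      n_reactions = length(m$reactions),
      imbalanced_reactions = as.list(
        if (spec$include_imbalanced) "R_atph_bad" else character(0)),
      undetermined_reactions = list(),
      exchange_reactions = as.list(intersect(names(rxns), "R_ex_glc")),
      missing_structure = as.list(sort(setdiff(all_ids,
        annotated[vapply(annotated, function(i)
          !is.null(FIXTURE_VOCAB[[i]]$smiles) || !is.null(FIXTURE_VOCAB[[i]]$inchi),
          logical(1))]))),
      missing_xref = as.list(sort(setdiff(all_ids, annotated))),
      duplicate_name_groups = if (spec$include_ambiguous)
        list(list("glc", "glc_dup")) else list(),
      peptide_metabolites = as.list(
        if (spec$include_peptides) "glygly" else character(0)),
      files = list(sbml = "model.sbml", metabolites = "metabolites.tsv",
                   reactions = "reactions.tsv", mapping = "mapping.json",
                   kgml = "pathway.kgml", chebi_table = "chebi.tsv",
                   kegg_table = "kegg.tsv", index_config = "index_config.json",
                   registry = "registry.json", residues = "residues.tsv"))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
               file.path(dir, "manifest.json"))
    invisible(manifest)
  })
}
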