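# Peptide assembly from metabolite names.
#
# Reconstructions modelling peptidoglycan synthesis contain di- and
# tripeptides that chemical databases rarely list, although the individual
# residues are always available. Peptide structures are therefore built by
# condensation from a residue table: the 20 canonical L-amino acids with
# three-letter codes, "-yl" combining names, free-amino-acid formulas and
# SMILES chain templates (user-extensible via a table file).

#' Load the amino-acid residue table
#'
#' Tab-separated table with columns `code` (three-letter key), `combining`
#' (the "-yl" combining name used inside peptide names), `full_names`
#' (`|`-separated full names accepted for the C-terminal residue),
#' `formula` (free amino acid) and `smiles_template` (N-to-C chain
#' fragment, ending in the carbonyl that forms the next amide bond). The
#' bundled table covers the 20 canonical L-amino acids.
#'
#' @param path Optional path to a user table with the same columns.
#' @return Named list of residues keyed by code, class `mm_residue_table`.
#' @export
residue_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "residues.tsv", package = "metanno")
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  res <- list()
  for (i in seq_len(nrow(df))) {
    res[[df$code[i]]] <- list(
      code = df$code[i],
      combining = tolower(df$combining[i]),
      full_names = tolower(trimws(strsplit(df$full_names[i], "|", fixed = TRUE)[[1]])),
      formula = parse_formula(df$formula[i]),
      smiles_template = df$smiles_template[i])
  }
  structure(res, class = "mm_residue_table")
}

#' Parse a peptide name into residue keys
#'
#' Recognizes two naming conventions: (a) the hyphenated code form
#' (`"Gly-Gly"`, `"Ala-Gly-Ser"`; case-insensitive three-letter codes) and
#' (b) the combining form (`"glycylglycine"`, `"L-alanyl-L-glutamate"`),
#' where each non-final residue carries its `-yl` combining name and the
#' final residue its full name. Stereo prefixes `L-`/`D-` are stripped and
#' recorded in the `stereo` attribute. Combining-name segmentation is
#' greedy longest-match left-to-right; if the whole name cannot be
#' consumed, or any token is not in the residue table, the name is not a
#' peptide and `NULL` is returned.
#'
#' @param name Metabolite name.
#' @param table Residue table from [residue_table()].
#' @return Character vector of residue codes in N-to-C order, or `NULL`.
#' @examples
#' parse_peptide_name("Gly-Gly")
#' parse_peptide_name("glycylglycine")
#' parse_peptide_name("glucosylglycine")  # NULL: no residue "glucosyl"
#' @export
parse_peptide_name <- function(name, table = residue_table()) {
  stopifnot(is.character(name), nzchar(name))
  codes <- names(table)

  # (a) hyphenated code form
  tokens <- tolower(trimws(strsplit(name, "-", fixed = TRUE)[[1]]))
  tokens <- tokens[nzchar(tokens)]
  stereo <- tokens[tokens %in% c("l", "d")]
  resid_tokens <- tokens[!tokens %in% c("l", "d")]
  if (length(resid_tokens) >= 2 && all(resid_tokens %in% codes)) {
    out <- resid_tokens
    attr(out, "stereo") <- stereo
    return(out)
  }

  # (b) combining form: strip stereo prefixes, drop hyphens/spaces, segment
  lowered <- tolower(name)
  stereo <- regmatches(lowered, gregexpr("(?<=^|-)[ld](?=-)", lowered, perl = TRUE))[[1]]
  stripped <- gsub("(^|-)[ld]-", "\\1", lowered)
  compact <- gsub("[- ]", "", stripped)
  combining <- vapply(table, `[[`, character(1), "combining")
  combining <- combining[order(-nchar(combining))]  # longest match first
  full_map <- list()
  for (r in table) for (fn in r$full_names) full_map[[gsub("[- ]", "", fn)]] <- r$code

  seq_codes <- character(0)
  rest <- compact
  repeat {
    if (rest %in% names(full_map)) {  # terminal residue consumes the rest
      seq_codes <- c(seq_codes, full_map[[rest]])
      attr(seq_codes, "stereo") <- stereo
      return(seq_codes)
    }
    hit <- NULL
    for (j in seq_along(combining)) {
      if (startsWith(rest, combining[j])) { hit <- j; break }
    }
    if (is.null(hit)) return(NULL)
    seq_codes <- c(seq_codes, names(combining)[hit])
    rest <- substr(rest, nchar(combining[hit]) + 1L, nchar(rest))
    if (!nzchar(rest)) return(NULL)  # ended on a combining name: not a peptide
  }
}

#' Assemble a peptide structure by condensation
#'
#' Chains residue SMILES templates through amide bonds N-to-C and computes
#' the exact element counts as the sum of the free-amino-acid formulas
#' minus one water per peptide bond:
#' `elements(peptide) = sum(elements(residues)) - (n-1) * {H2, O}`.
#' The structure is emitted in the neutral (uncharged) protonation state.
#'
#' @param residues Character vector of residue codes, length >= 2.
#' @param table Residue table from [residue_table()].
#' @return An `mm_structure` with SMILES, formula and formal charge 0.
#' @examples
#' s <- assemble_peptide(c("gly", "gly"))
#' format_formula(s$formula)  # "C4H8N2O3"
#' @export
assemble_peptide <- function(residues, table = residue_table()) {
  if (length(residues) < 2)
    stop("peptide assembly needs at least 2 residues", call. = FALSE)
  unknown <- setdiff(residues, names(table))
  if (length(unknown) > 0)
    stop("unknown residue key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  total <- ec_clean(c())
  for (code in residues)
    total <- formula_combine(total, table[[code]]$formula, 1L, +1L)
  water <- c(H = 2L, O = 1L)
  total <- formula_combine(total, water, length(residues) - 1L, -1L)
  smiles <- paste0(paste(vapply(residues, function(code)
    table[[code]]$smiles_template, character(1)), collapse = ""), "O")
  chemical_structure(smiles = smiles, formula = total, charge = 0L)
}
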