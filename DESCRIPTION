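Package: metanno
Title: Annotation of Genome-Scale Metabolic Models with Cross References and Chemical Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for annotating genome-scale metabolic models
    with MIRIAM-encoded database cross references and chemical structures
    (InChI/SMILES). Imports models from SBML, delimited spreadsheet tables and
    minimal KGML; infers the resource a bare identifier belongs to from a
    bundled registry snapshot; builds a local searchable index over chemical
    resource tables and serves exact and ranked fuzzy name queries; assembles
    di- and polypeptide structures from metabolite names; parses and formats
    human-readable reaction equations with exact rational stoichiometry; and
    checks per-reaction mass and charge balance. Annotated models are exported
    as SBML Level 3 with identifiers.org CV terms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
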