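# metanno

Headless annotation tooling for genome-scale metabolic models (GSMMs).

Draft reconstructions routinely circulate as spreadsheets or sparsely
annotated SBML, where a metabolite is just a name. That blocks two things
curators need: unambiguous identification of model components (for
integration with other datasets and databases) and verification that every
reaction conserves mass and charge — a prerequisite for constraint-based
analysis, and one that hinges on knowing each metabolite's formula and
protonation state. `metanno` closes that gap offline: it attaches
MIRIAM-encoded database cross references (resolvable identifiers.org URIs)
and chemical structures (InChI/SMILES) to model species, then audits the
result.

What it does:

* **Import** from SBML Level 2/3, delimited spreadsheet tables with an
  explicit column mapping, and minimal KGML; **export** annotated SBML
  Level 3 with RDF CV terms (`bqbiol:is` + identifiers.org URIs) and
  COBRA-style notes (`FORMULA:`, `CHARGE:`, `INCHI:`, ...).
* **Infer the resource** a bare identifier belongs to (`"C00002"` →
  `kegg.compound`) by pattern-matching against a bundled, versioned MIRIAM
  registry snapshot; ambiguity is surfaced, never silently resolved.
* **Index** local chemical resource tables (or SDF tag fields) and serve
  exact and ranked fuzzy name queries. Ranking uses Jaccard similarity of
  character trigrams on normalized names (case-folded, Greek letters
  spelled out, punctuation collapsed): for names *a*, *b* with trigram
  sets *T(a)*, *T(b)*,

  > score(a, b) = |T(a) ∩ T(b)| / |T(a) ∪ T(b)|

* **Annotate** structure-less metabolites along an automated-to-manual
  gradient: transfer from imported notes → cross-reference lookup → name
  search (silent only on unique exact matches; ranked suggestions
  otherwise) → peptide assembly. Every action and refusal is logged as a
  JSON-lines decision; structures are never overwritten.
* **Assemble di-/polypeptides** from names like `Gly-Gly` or
  `L-alanyl-L-glutamate` by condensation over a 20-residue table:
  elements(peptide) = Σ elements(residues) − (n−1)·{H₂O}, SMILES chained
  N-to-C, neutral protonation state.
* **Check consistency**: per-reaction element and charge deltas (products
  minus reactants) in exact rational arithmetic, plus model-wide lists of
  metabolites lacking structures or cross references and duplicate-name
  groups.

## Worked example

```r
library(metanno)

# a deterministic toy bundle: SBML + tables + resource index inputs
dir <- tempfile()
generate_fixtures(fixture_spec(seed = 1), dir)

m <- read_sbml(file.path(dir, "model.sbml"))
m
#> <model> fixture_model: 15 metabolites, 5 reactions, 1 compartments

# which database does a hand-entered identifier belong to?
infer_resource("C00002", read_registry())
#> [1] "kegg.compound"

# mass/charge audit: the bundle deliberately ships one broken reaction
rep <- model_report(m)
rep
#> Model consistency report
#>   reactions: 5 (1 imbalanced, 0 undetermined, 1 exchange)
#>   metabolites: 15 (7 without structure, 7 without cross reference)
#>   duplicate-name groups: 1
#> R_atph_bad: imbalanced  elements: H-1  charge: -1

# the injected defect is ATP hydrolysis with the proton omitted:
element_balance("R_atph_bad", m)
#>  H
#> -1

# annotate: notes transfer, xref lookup, name search, peptide assembly
idx <- file.path(dir, "index.json")
cmd_index(file.path(dir, "index_config.json"), idx)
cmd_annotate(file.path(dir, "model.sbml"), "sbml", idx,
             file.path(dir, "annotated.sbml"))
#> annotate: 7 decision(s), 7 accepted

# the dipeptide got its structure from its name, not from any database:
ann <- read_sbml(file.path(dir, "annotated.sbml"))
format_formula(metanno:::entity_formula(ann$metabolites$glygly)$formula)
#> [1] "C4H8N2O3"
```

`H-1` means the products are short one hydrogen relative to the reactants
(and the charge delta −1 matches): the classic symptom of a dropped
proton. `C4H8N2O3` is glycylglycine assembled as 2 × C2H5NO2 − H2O.

A shell interface with subcommands `convert`, `index`, `annotate`,
`check` and `fixtures` is installed at `inst/cli/metanno`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","metanno",package="metanno"))')" \
  check --in model.sbml     # exit 1 iff an imbalanced reaction exists
```

## Not in scope

Live web-service lookups, genome/gene-product import, thermodynamic
estimation, structure depiction and substructure search, atom–atom
mapping, and automatic rebalancing (the checker reports; it never mutates
the model).
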