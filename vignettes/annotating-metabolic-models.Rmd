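---
title: "Annotating genome-scale metabolic models with metanno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating genome-scale metabolic models with metanno}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metanno)
```

## The problem

A genome-scale metabolic model is only as useful as the identity of its
components. A species element that says `M_atp_c` identifies nothing; a
cross reference to a database entry identifies it conditionally (the
entry may be behind a paywall, may have disappeared, or may describe a
different protonation state); a chemical structure identifies it
unconditionally. Protonation matters because constraint-based analysis
presumes every reaction conserves mass and charge, and the formula and
charge of, say, ATP differ between its neutral and 4− forms. `metanno`
is a headless toolkit for attaching both kinds of annotation — database
cross references encoded against the MIRIAM registry, and structures as
InChI/SMILES — and for auditing the result.

This vignette records the package's model of the task, the tunable
parameters, the numerical and design choices that were genuinely open,
and what the test suite does and does not demonstrate.

## The annotation model

Every metabolite and reaction carries an ordered multiset of annotations
of six kinds: `crossref`, `structure`, `formula`, `charge`, `synonym`,
`note`. Multiple annotations of the same kind coexist (a metabolite can
reference ChEBI *and* KEGG); exact duplicates (same kind and value) are
stored once, which is what makes every annotation procedure idempotent.
A `structure` annotation carries exactly one line notation. InChIs are
partially interpreted — element counts and net charge are derived from
the formula and `/q` layers — while SMILES are carried opaquely: the
package embeds no molecular-graph perception, and nothing downstream
requires it, because balance checking runs on formulas and charges.
When several sources disagree, precedence is curator-first: an explicit
formula annotation outranks a structure-derived formula, and
disagreement itself is reported as an inconsistency rather than silently
resolved.

## Cross references and the registry snapshot

Resource inference and URI encoding run against a bundled, versioned
JSON snapshot of namespace patterns (20 namespaces: ChEBI, KEGG
compound/reaction/drug, HMDB, PubChem compound/substance, MetaCyc, SEED,
BiGG, MetaNetX, LIPID MAPS, InChIKey, EC, UniProt, Rhea, GO, SBO,
Reactome, NCBI Taxonomy), not a live web registry: annotation runs must
be reproducible offline, and a registry that changes under the user is
worse than one that is slightly stale. Users may substitute their own
snapshot; the snapshot version used is recorded in a comment in exported
SBML.

`infer_resource()` returns *every* namespace whose anchored pattern
matches, with literal-prefix matches (e.g. `CHEBI:`) ranked first. Bare
digit strings genuinely are ambiguous (PubChem, Rhea, Taxonomy, ...);
the design decision is that ambiguity is surfaced to the caller and
never resolved by guessing. Legacy `urn:miriam:` URNs decode through a
namespace alias table (`obo.chebi` → `chebi`) with percent-decoding.

## Exact arithmetic

Stoichiometric coefficients are reduced integer `num/den` pairs, so a
0.5-coefficient reaction balances exactly rather than to within
floating-point error. Element balance is computed per element as
Σ products − Σ reactants of coefficient × count, in rational arithmetic.
Decimal-representable rationals print exactly (`0.5`), others print as
fractions (`1/3`). One consequence is documented as a limitation: SBML
stoichiometry attributes are decimal doubles, so coefficients like 1/3
survive in memory but round-trip through SBML only to 17 significant
digits; every fixture and the equation corpus use decimal-representable
coefficients.

Formula parsing accepts any `[A-Z][a-z]?` symbol without a periodic
table, so placeholder elements (`R`, `X`) in draft models parse; the
checker classifies reactions touching them as *undetermined* — you
cannot assert conservation over unknowns — rather than rejecting them.
One-sided exchange reactions are classified *exchange* and exempted:
they are unbalanced by construction. The equation grammar requires the
empty side to be explicit (`∅` or `nothing`) so that a truncated
equation is an error, not an exchange.

## Name matching

Names are normalized by case folding, spelling out Greek letters
(α → alpha), and collapsing runs of whitespace, hyphens, commas and
parentheses. Fuzzy ranking is Jaccard similarity over character trigrams
of normalized names, taking the maximum over primary name and synonyms.
The metric was an open choice; trigram Jaccard was fixed because it is
deterministic, needs no training data, and handles the dominant failure
mode (synonym drift in punctuation and stereo-prefix placement). Names
shorter than three characters have no trigrams and fall back to exact
matching. Ties break by namespace, then identifier, lexicographically —
arbitrary but deterministic. The suggestion threshold defaults to 0.5;
at that level trivially related sugar names fall well below
(glucose/fructose score 0.1) and near-identical spellings survive. Silent assignment
requires a *unique* exact normalized match: two records sharing a
normalized name block silent attachment by design, because a wrong
silent assignment is far costlier than a skipped one.

## The annotation pipeline

The pipeline order — notes transfer, then cross-reference lookup, then
name search, then peptide assembly — runs from most to least reliable
evidence, and is overridable. Two invariants hold everywhere: a
structure is attached only into an empty structure slot (conflicts
surface as rejected decisions, nothing is overwritten), and re-running
any step on its own output produces zero new decisions. Interactivity is
replaced by a review cycle: suggest-mode candidates are written to a
JSON-lines decision log with scores and `accepted = false`; a human (or
script) flips flags; `apply_decisions()` attaches the confirmed records.

The SBML reader types recognized notes lines (`FORMULA:`, `CHARGE:`,
`INCHI:`, ...) into annotations by default, which is what makes
write→read round-trips exact. For models whose notes should be audited
explicitly, `read_sbml(extract_notes = FALSE)` keeps every line verbatim
and `transfer_structures()` performs the promotion with one logged
decision per transfer. The key-alias table is a superset of common
COBRA-style keys and is user-extensible; which keys the original
desktop tools recognized is not documented anywhere, so the table is an
artifact-defined choice.

## Peptide assembly

Reconstructions that model peptidoglycan synthesis contain dipeptides
that structure databases rarely list, though the residues are always
available. Names are recognized in two conventions: hyphenated
three-letter codes (`Gly-Gly`) and combining names
(`glycylglycine`, `L-alanyl-L-glutamate`), with `L-`/`D-` prefixes
stripped and recorded. Combining-name segmentation is greedy
longest-match, left to right, and must consume the whole name; the
greedy rule avoids false positives on sugar `-yl` names
(`glucosylglycine` fails because `glucosyl` is not a residue). The
assembled structure's element counts are Σ residue formulas minus one
water per peptide bond; the SMILES chains residue templates N-to-C and
the neutral protonation state is emitted (models wanting zwitterions
adjust via a charge annotation) because neutral forms keep the formula
bookkeeping deterministic. The bundled table covers the 20 canonical
L-amino acids and can be replaced by a user table.

## The fixture generator

`generate_fixtures()` emulates, at desk scale, every input the pipeline
consumes: an SBML model, the same model as spreadsheet tables with a
column mapping, a KGML snippet, per-resource chemical tables, and copies
of the registry and residue tables. Chemistry comes from a fixed
vocabulary of 14 real metabolites with literature-standard formulas and
anion-convention charges (ATP⁴⁻, HPO₄²⁻, ...), so balance tests run
against genuine stoichiometry; reactions are drawn from a fixed pool of
five (ATP hydrolysis, hexokinase, glycylglycine synthesis, glucose
oxidation, a glucose exchange). Defaults: 14 metabolites, 5 reactions,
60% of metabolites annotated with cross references and structures
(formulas and charges are always present, so balance status stays
determined), one injected imbalanced reaction (ATP hydrolysis minus its
proton: element delta {H: −1}, charge −1), one structure-less
peptide-named metabolite, one ambiguously named pair. Every defect is
listed in a manifest, and the consistency report is tested to equal the
manifest exactly across seeds.

What the generator does **not** emulate — and what passing tests
therefore do not show — includes genome-scale size (thousands of
species), the notes-dialect zoo of real published SBML, inconsistent or
legacy identifier spellings beyond the alias table, multi-compartment
transport chemistry, and resource tables with conflicting entries for
the same compound. The test suite demonstrates correctness of the
mechanisms on faithful miniatures, not recall on any particular
published reconstruction.

## Problem sizes used in the checks

The acceptance checks sweep all 400 dipeptides and 8000 tripeptides over
the residue table against an independently computed element-sum oracle,
round-trip 20 generated models through SBML, invert URIs for a
50-identifier set spanning all 20 namespaces, verify ranked-search
scores against a brute-force trigram enumeration on 100 query/record
pairs, and run the annotation pipeline twice on generated bundles to
confirm the second run decides nothing. These sizes were chosen to
exhaust the combinatorial claims (the peptide law and URI inversion are
checked exhaustively over their domains) while keeping the whole suite
in well under a minute.

## Known limitations

* SMILES are not interpreted; a SMILES-only structure contributes no
  formula, and balance then depends on an explicit formula annotation.
* InChI interpretation covers the formula and charge layers only.
* Non-decimal rationals lose exactness through SBML (above).
* Spreadsheet import reads delimited text (CSV/TSV); binary workbook
  formats should be exported to CSV first.
* KGML import is deliberately minimal: compound entries and reactions,
  no graphics, no gene entries.
* The checker only reports; proton/water rebalancing suggestions are out
  of scope, as are merging of reconciled databases, substructure search
  and thermodynamic estimation.
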