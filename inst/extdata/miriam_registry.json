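{
  "format": "metanno-registry",
  "version": "2026.1",
  "entries": [
    {"namespace": "chebi", "display_name": "ChEBI", "pattern": "^CHEBI:\\d+$", "uri_base": "https://identifiers.org/chebi/", "id_prefix": "CHEBI:", "aliases": ["obo.chebi"]},
    {"namespace": "kegg.compound", "display_name": "KEGG Compound", "pattern": "^C\\d{5}$", "uri_base": "https://identifiers.org/kegg.compound/", "aliases": ["kegg.cpd"]},
    {"namespace": "kegg.reaction", "display_name": "KEGG Reaction", "pattern": "^R\\d{5}$", "uri_base": "https://identifiers.org/kegg.reaction/"},
    {"namespace": "kegg.drug", "display_name": "KEGG Drug", "pattern": "^D\\d{5}$", "uri_base": "https://identifiers.org/kegg.drug/"},
    {"namespace": "hmdb", "display_name": "Human Metabolome Database", "pattern": "^HMDB\\d{4,7}$", "uri_base": "https://identifiers.org/hmdb/", "id_prefix": "HMDB"},
    {"namespace": "pubchem.compound", "display_name": "PubChem Compound", "pattern": "^\\d+$", "uri_base": "https://identifiers.org/pubchem.compound/"},
    {"namespace": "pubchem.substance", "display_name": "PubChem Substance", "pattern": "^\\d+$", "uri_base": "https://identifiers.org/pubchem.substance/"},
    {"namespace": "metacyc.compound", "display_name": "MetaCyc Compound", "pattern": "^CPD-\\d+$", "uri_base": "https://identifiers.org/metacyc.compound/", "id_prefix": "CPD-", "aliases": ["biocyc"]},
    {"namespace": "seed.compound", "display_name": "SEED Compound", "pattern": "^cpd\\d{5}$", "uri_base": "https://identifiers.org/seed.compound/", "id_prefix": "cpd"},
    {"namespace": "bigg.metabolite", "display_name": "BiGG Metabolite", "pattern": "^[a-z][a-z0-9_]+$", "uri_base": "https://identifiers.org/bigg.metabolite/"},
    {"namespace": "metanetx.chemical", "display_name": "MetaNetX Chemical", "pattern": "^MNXM\\d+$", "uri_base": "https://identifiers.org/metanetx.chemical/", "id_prefix": "MNXM"},
    {"namespace": "lipidmaps", "display_name": "LIPID MAPS", "pattern": "^LM[A-Z]{2}\\d{8}$", "uri_base": "https://identifiers.org/lipidmaps/", "id_prefix": "LM"},
    {"namespace": "inchikey", "display_name": "InChIKey", "pattern": "^[A-Z]{14}-[A-Z]{10}-[A-Z]$", "uri_base": "https://identifiers.org/inchikey/"},
    {"namespace": "ec-code", "display_name": "Enzyme Nomenclature", "pattern": "^\\d+(\\.(\\d+|-)){3}$", "uri_base": "https://identifiers.org/ec-code/", "aliases": ["ec", "obo.ec-code"]},
    {"namespace": "uniprot", "display_name": "UniProt Knowledgebase", "pattern": "^[OPQ][0-9][A-Z0-9]{3}[0-9]$|^[A-NR-Z][0-9][A-Z][A-Z0-9]{2}[0-9]$", "uri_base": "https://identifiers.org/uniprot/"},
    {"namespace": "rhea", "display_name": "Rhea", "pattern": "^\\d{5}$", "uri_base": "https://identifiers.org/rhea/"},
    {"namespace": "go", "display_name": "Gene Ontology", "pattern": "^GO:\\d{7}$", "uri_base": "https://identifiers.org/go/", "id_prefix": "GO:", "aliases": ["obo.go"]},
    {"namespace": "sbo", "display_name": "Systems Biology Ontology", "pattern": "^SBO:\\d{7}$", "uri_base": "https://identifiers.org/sbo/", "id_prefix": "SBO:", "aliases": ["biomodels.sbo"]},
    {"namespace": "reactome", "display_name": "Reactome", "pattern": "^R-[A-Z]{3}-\\d+$", "uri_base": "https://identifiers.org/reactome/", "id_prefix": "R-"},
    {"namespace": "taxonomy", "display_name": "NCBI Taxonomy", "pattern": "^\\d+$", "uri_base": "https://identifiers.org/taxonomy/"}
  ]
}
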