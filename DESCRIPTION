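Package: pdbmine
Title: Mining Protein Data Bank Identifiers and Ontology Terms from Full-Text Literature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Text-mining pipeline for full-text open-access articles in
    NLM/JATS XML. Detects candidate Protein Data Bank (PDB) accession codes
    by pattern matching, validates them against an identifier lexicon,
    applies a false-positive blacklist with contextual cue criteria, and
    records the surrounding paragraph or figure legend as mention context.
    Tags ontology terms from OBO dictionaries using the longest-possible-match
    rule. Aggregates mentions into structure-article association tables,
    ranks structures by literature frequency, lists co-occurring structures,
    and annotates co-occurring pairs with best-chain global-alignment percent
    identity. Includes a seeded synthetic-corpus generator (articles,
    lexicons, ontologies, chain FASTA) with machine-readable ground truth for
    end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'pdbmine-package.R'
    'jats.R'
    'mine.R'
    'association.R'
    'export.R'
    'ontology.R'
    'fixtures.R'
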