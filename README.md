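# pdbmine

Text mining of full-text open-access literature for Protein Data Bank
(PDB) structure identifiers and ontology terms.

## The problem

Structural biologists want to know every article that discusses a given
PDB entry — including articles that mention the accession code in passing
without formally citing the structure's primary publication. Full-text
archives in NLM/JATS XML make that possible, but naive pattern matching
drowns in false positives: PDB accessions are four characters (a digit
followed by three alphanumerics), so ordinary tokens such as years,
catalogue numbers, and product names collide with real accessions. The
canonical example is `3DNA`, a valid PDB entry that is also the name of a
software package and of a wet-lab kit.

`pdbmine` implements the full pipeline for this problem, aimed at
bioinformaticians curating literature–structure links:

1. **Corpus parsing** — JATS/NLM article XML is decomposed into minable
   text units (title, abstract paragraphs, body paragraphs, figure
   captions), with inline markup flattened and whitespace normalised so
   character offsets are stable. Tables and reference lists are excluded:
   the interesting mentions are the ones *outside* the formal reference
   list.
2. **Identifier mining** — candidate tokens matching
   `[1-9][A-Za-z0-9]{3}` (word-bounded, at least one letter, so all-digit
   years never qualify) are validated against a lexicon of real PDB ids.
   Ids on a false-positive blacklist are accepted only when a contextual
   cue term ("PDB", "Protein Data Bank", "accession", "structure",
   "crystal structure") occurs in the same text unit. Every surviving
   mention records its offsets and its display context: the surrounding
   paragraph, or the figure legend for caption mentions.
3. **Ontology tagging** — dictionaries built from OBO ontologies (term
   names + EXACT synonyms) are matched with the *longest-possible-match*
   rule: at each token position the longest matching dictionary entry
   wins and the scan resumes after it.
4. **Association analysis** — mentions aggregate into a structure–article
   association table; structures are ranked by distinct-article count;
   co-occurring ids (structures sharing an article) are listed and
   annotated with the best-chain pairwise percent identity, computed by
   Needleman–Wunsch global alignment (match +1, mismatch −1, linear gap
   −1; identity = matches / alignment columns, gap columns included).
   For multi-chain entries the chain pair with the highest identity is
   reported.
5. **Exports** — per-article metadata and figure-list payloads as
   key-sorted JSON files, plus annotated article XML in which each
   mention and term span is wrapped in an inline element; stripping the
   annotations recovers the original text byte-for-byte.

A seeded synthetic-corpus generator (`generateCorpus`, `generateOBO`,
`generateChainFasta`, `generateLexicon`) produces JATS articles with
planted identifiers, decoy tokens, planted ontology terms, and related
chain sequences, together with a machine-readable ground-truth manifest —
so the whole pipeline is testable end to end without downloading
anything.

## Worked example

```r
library(pdbmine)

xml <- paste0(
  '<article><front><article-meta>',
  '<article-id pub-id-type="pmc">1483839</article-id>',
  '<title-group><article-title>Inhibitor recognition by a retroviral ',
  'protease</article-title></title-group>',
  '<abstract><p>We compare our model with the crystal structure 1HIV.</p></abstract>',
  '</article-meta></front><body>',
  '<p>Coordinates were taken from PDB entry 1HIV and compared with 3BY7.</p>',
  '<p>Duplex geometry was generated with the 3DNA software package.</p>',
  '<fig id="f1"><label>Figure 1</label><caption><p>Overall fold of 1HIV ',
  'bound to the inhibitor.</p></caption></fig>',
  '</body></article>')

art <- parseJATS(xml)
lex <- IdLexicon(c("1HIV", "3BY7", "3DNA"), blacklist = "3DNA")
men <- mineArticle(art, lex)
men[, c("pdb_id", "unit_id", "unit_kind", "start", "end", "cue_found")]
#>   pdb_id unit_id     unit_kind start end cue_found
#> 1   1HIV   abs-1 abstract_para    48  52      TRUE
#> 2   1HIV     p-1     body_para    38  42      TRUE
#> 3   3BY7     p-1     body_para    61  65      TRUE
#> 4   1HIV  cap-f1       caption    16  20     FALSE
```

Four mentions survive: `1HIV` in the abstract, body and figure caption,
and `3BY7` in the body. The `3DNA` token in the second paragraph is
*filtered*: it is blacklisted and its unit ("... generated with the 3DNA
software package") contains no cue term. Had the sentence read "PDB entry
3DNA", it would have been kept. The caption mention's context is the
figure legend itself.

```r
buildAssociations(men)
#> AssociationTable: 2 PDB ids across 1 articles (2 pairs)

sequenceIdentity("HEAGAWGHEE", "PAWHEAE")
#> [1] 45.45455
#> attr(,"score")    -1
#> attr(,"matches")   5
#> attr(,"columns")  11
```

The identity is 5 matching columns over 11 alignment columns of the
optimal global alignment (score −1 under +1/−1/−1 scoring).

A command-line driver with verbs `mine`, `tag`, `query`, `figures`,
`rank` and `simulate` ships in `inst/scripts/pdbmine-cli.R`:

```sh
Rscript inst/scripts/pdbmine-cli.R simulate --n 100 --seed 3 --out corpus/
Rscript inst/scripts/pdbmine-cli.R mine --corpus corpus/ \
    --lexicon corpus/lexicon.txt --blacklist corpus/blacklist.txt --out out/
```

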