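---
title: "Mining PDB identifiers and ontology terms from full-text articles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining PDB identifiers and ontology terms from full-text articles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdbmine)
```

# The method

`pdbmine` links macromolecular structures to the open-access literature
that discusses them. The unit of evidence is a *mention*: an occurrence
of a valid PDB accession code inside a text unit of a full-text article,
validated against the set of real accessions and filtered for the
vocabulary collisions that four-character codes inevitably produce.
Corpus-level aggregation of mentions yields the structure–article
association table, frequency rankings, and co-occurrence lists that are
the pipeline's end products.

## Corpus model

Articles arrive as NLM/JATS XML, the format full-text archives
distribute. `parseJATS()` reduces an article to an ordered list of text
units — title, abstract paragraphs, body paragraphs, figure captions —
plus a figure table and the copyright note. Three parsing decisions
matter downstream:

* **Lenient tag handling.** Both NLM 2.x and JATS 1.x element names are
  accepted; unrecognised inline elements (`italic`, `bold`, `sub`,
  `sup`, `xref`, ...) are descended into and flattened to their text,
  because archive content spans DTD generations.
* **Whitespace normalisation.** Runs of whitespace collapse to single
  spaces and units are trimmed. Every offset the pipeline reports
  (mention spans, term spans) is measured on this normalised text, so
  offsets are stable regardless of how the XML was pretty-printed.
* **Exclusions.** Paragraphs inside tables, reference lists and boxed
  text are not text units. Mentions in formal reference lists are
  precisely the ones the method does *not* need to find — its value lies
  in mentions outside the citation apparatus — and table mining has
  failure modes (cell fragments, headers) that deserve their own
  treatment. Titles and abstracts *are* mined: a mention there is the
  strongest kind of evidence. Supplementary sections are out of scope.

## Candidate detection and validation

A candidate is a word-bounded token of exactly four characters, first
character a digit 1–9, remaining three alphanumeric with at least one
letter. The digit-first constraint mirrors the real accession space; the
at-least-one-letter constraint removes every all-digit token, which
eliminates calendar years — the dominant false-positive class — before
any lexicon is consulted. "Word-bounded" means not adjacent to an
alphanumeric character; hyphens and underscores count as boundaries, so
`PDB:1HIV`, `(1hiv)` and `1HIV-bound` all yield candidates. Matching is
case-insensitive and the canonical stored form is uppercase.

Candidates survive only if present in the identifier lexicon
(`IdLexicon`), a plain-text list of the real accession universe. An
empty lexicon is a configuration error, not an empty result: validation
without a lexicon is meaningless.

## The false-positive blacklist

Some valid accessions are also ordinary product or software names
(`3DNA` is the classic case). Such ids go on a blacklist and are held to
a stricter standard: a mention is kept only when a cue term occurs,
case-insensitively, somewhere in the same text unit. The shipped cue set
is "PDB", "Protein Data Bank", "accession", "structure", "crystal
structure"; it is configuration, not code. Same-unit cue presence was
chosen over sentence-level or distance-based rules because it is the
simplest criterion that is fully auditable — every filtered candidate is
logged with its unit id — and because paragraph-sized units keep the cue
close enough to be evidence. Every returned mention carries a
`cue_found` flag, so downstream consumers can apply stricter policies
retroactively.

Duplicate mentions of one id within a unit are all recorded;
deduplication happens at association level, where the per-article
mention count is kept alongside the article set.

## Context extraction

A mention's display context is the full text of its containing unit: the
surrounding paragraph for body and abstract mentions, and the figure
legend for caption mentions. Captions are deliberately a separate unit
kind because the legend, not the paragraph that references the figure,
is what a reader needs to interpret a mention inside a figure.

## Ontology tagging and the longest-possible-match rule

Dictionaries are built from OBO 1.2 ontologies: one entry per term name
and per EXACT synonym, obsolete terms skipped. BROAD, NARROW and RELATED
synonyms are excluded — they trade recall for precision in exactly the
wrong direction for automatic markup.

Tagging scans left to right over token boundaries. At each position the
longest dictionary entry that matches (measured in tokens) is emitted
and the scan resumes after it, so "zinc finger" suppresses "zinc" at the
same position, and matches within one ontology never overlap. When
several ontologies match the same span, each contributes its own tag.

Two normalisation choices are deliberate and narrower than they might
appear:

* **Tokenisation** splits on non-alphanumeric characters, and matching
  is token-boundary aligned: "cat" can never match inside "catalysis".
* **Canonical surface form** is the lowercased token sequence joined by
  single spaces, applied to both dictionary entries and text spans. This
  makes "Zinc-Finger" in text equal to the entry "zinc finger" — a
  strict refinement of plain lowercase-and-collapse normalisation that
  makes multi-word matching well defined across punctuation. No
  stemming and no plural folding are applied: both would need
  per-ontology evidence to justify.

Ties at equal token count cannot produce distinct spans under this
normalisation; duplicate surfaces within one ontology are resolved at
dictionary build time in favour of the lexicographically smallest term
id, a deterministic and documented tie-break.

## Associations, ranking, co-occurrence

`buildAssociations()` aggregates mentions into one row per (id, article)
pair with its mention count. The by-id and by-article views are
transposes by construction, and the conservation identity (both views
enumerate the same pair set) is asserted in tests. Ranking counts
*distinct articles*, not total mentions, with lexicographic tie-breaks.
Co-occurring ids — other structures mentioned in the same articles — are
sorted by shared-article count, then id.

## Sequence identity

Co-occurring pairs are annotated with pairwise percent identity so the
user can tell whether two structures share an article because they are
related molecules or merely related topics. The measure is
Needleman–Wunsch global alignment with match +1, mismatch −1, linear gap
penalty −1, and identity defined as matching columns divided by *all*
alignment columns, gap columns included — the conservative denominator
convention, stated explicitly because conventions differ. Scoring
parameters are arguments, not constants.

Optimal alignments are generally not unique, and different optima can
have different identities. The contract is therefore tie-explicit: the
traceback resolves score ties as diagonal first, then up (consuming the
first sequence), then left, and the reported identity is that of this
single reproducible alignment. The test suite checks the implementation
against exhaustive enumeration of every alignment of short pairs,
selecting the enumerated optimum under the same tie order.

For multi-chain entries, `bestChainSimilarity()` maximises identity over
the chain cross-product and reports the best pair, ties broken by chain
name. Chain sequences are supplied externally as FASTA with
`PDBID_CHAIN` headers; the package does not parse structure files. Exact
dynamic programming is appropriate at this scale (chains of hundreds of
residues, handfuls of chains); heuristic aligners would buy nothing.

## Exports

Payloads mirror two web-service shapes as files: per-article metadata
(title, abstract, license note, and the mentions of the queried id with
their contexts) and per-article figure lists, both with sorted keys so
serialisation is byte-deterministic. Annotated XML wraps each mention
span in `<mention pdb-id="...">` and each term span in
`<term ontology="..." term-id="...">`; stripping annotations restores
the unit texts byte-identically. Where a term span overlaps a mention
span, the mention wins and the term is dropped with a log message —
identifier evidence outranks vocabulary markup.

# The synthetic-data generator

Real corpora cannot ship with a package, and mining accuracy can only be
measured against known ground truth, so the generator is first-class
code. `generateCorpus()` emits JATS articles built from a filler
vocabulary that deliberately contains no cue terms, no digits and no
ontology vocabulary, so every planted token is the only thing of its
kind in its unit and the manifest is exact. Each article receives:

* 2–4 planted mentions of lexicon ids (the corpus-level average of ~3
  per article), a quarter of them in figure captions; mentions of
  blacklisted ids are planted with a cue ("the PDB entry ...") and must
  survive;
* decoys at ~1.5 per article: year tokens, pattern-conformant tokens
  absent from the lexicon, and blacklisted ids in cue-less product-name
  sentences ("the ... software package") that must be filtered;
* optionally, planted ontology terms drawn from a generated OBO
  ontology whose names nest ("zinc", "zinc finger", "zinc finger
  domain") to exercise longest-match.

Generated text is already whitespace-normalised, so manifest offsets
re-locate exactly after parsing — the property that ties the generator
to the parser's offset convention. Generation is a pure function of the
seed (the caller's RNG state is saved and restored), and two runs with
one seed are byte-identical.

`generateChainFasta()` derives every chain from one random ancestor;
each non-ancestor chain receives Binomial(L, r) point substitutions at
distinct positions, so the gapless identity of a mutant to the ancestor
is exactly (L − m)/L and sits at 100·(1 − r) in expectation. The aligner
may report marginally higher identity when clustered mutations admit a
gapped optimum; tests assert the exact Hamming identity separately from
the sampling-tolerance check on the aligned identity.

What the generator does **not** emulate: realistic prose (filler
sentences are grammatically flat), the full JATS DTD surface (no
supplementary material, no nested floats groups), tables, citation
networks, OCR noise, or the empirical frequency distribution of real
accessions in real articles. Passing the synthetic benchmarks therefore
demonstrates the *mechanics* — detection, validation, filtering,
offsets, aggregation — not the field-realistic precision/recall of the
heuristics, which depend on a real corpus and a real blacklist.

# Evaluation sizes and numerical choices

The shipped evaluation runs 50 corpora of 100 articles (≈15,000 planted
mentions, ≈7,500 decoys in total), 1000 random texts against a 500-term
ontology with a brute-force tagging oracle, 500 short sequence pairs
against exhaustive alignment enumeration (lengths ≤ 6, where enumeration
is cheap), a 200-article random corpus for co-occurrence symmetry
against a double-loop oracle, and markup round-trips over a full corpus.
These sizes give every statistic a comfortable event count while keeping
the whole suite inside a couple of minutes on one core.

Degenerate inputs are defined, not accidental: empty text yields no
candidates; an unknown PDB id yields an empty co-occurrence list and an
empty payload list (a valid-but-unmentioned structure is not an error);
an empty lexicon, an empty chain set, an empty sequence, or a
non-amino-acid character is an argument/configuration error; an
impossible generator specification fails before any file is written.

# Known limitations

* The blacklist cue rule is unit-local; a cue in the neighbouring
  paragraph does not rescue a blacklisted mention. Manual review remains
  the only route to total accuracy.
* Chain-level and ligand-level sub-identifiers are not resolved; a
  mention links to the entry, not to a chain.
* The identity measure is a deterministic stand-in for whatever
  similarity a production site would precompute; its scoring is exposed
  as configuration so it can be matched to an external convention.
* No machine-learned disambiguation: every rule here is auditable by
  construction, which is the design priority.
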