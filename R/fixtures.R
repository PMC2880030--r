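#' @include mine.R ontology.R
NULL

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
# Keeps every generator a pure function of (parameters, seed).
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Filler vocabulary for synthetic prose.  Deliberately excludes every cue
# term ("PDB", "Protein Data Bank", "accession", "structure", "crystal
# structure"), contains no digits (so no pattern-conformant identifier
# tokens can arise by accident) and is disjoint from the ontology term
# vocabulary, so ground truth is exact.
.fillerVocab <- c(
  "the", "analysis", "reveals", "binding", "affinity", "between",
  "residues", "within", "conserved", "regions", "samples", "were",
  "prepared", "under", "native", "conditions", "and", "measured",
  "across", "replicates", "results", "indicate", "robust", "folding",
  "behaviour", "observed", "during", "refinement", "experiments",
  "confirm", "earlier", "observations", "reported", "previously",
  "model", "quality", "improved", "after", "iterative", "fitting")

# Vocabulary reserved for ontology term names.
.termVocab <- c(
  "zinc", "finger", "domain", "helix", "kinase", "receptor", "transport",
  "membrane", "signal", "loop", "motif", "alpha", "beta", "gamma",
  "catalytic", "pocket", "metal", "ion", "channel", "ligand", "sheet",
  "bundle", "barrel", "cluster", "repeat")

# Vocabulary reserved for exact synonyms (disjoint from both of the above).
.synVocab <- c("delta", "epsilon", "zeta", "theta", "kappa", "lambda",
               "sigma", "omega", "micro", "nano", "proximal", "distal")

.fillerWords <- function(n) {
  sample(.fillerVocab, n, replace = TRUE)
}

.randomPdbId <- function() {
  repeat {
    id <- paste0(sample(1:9, 1),
                 paste(sample(c(LETTERS, as.character(0:9)), 3,
                              replace = TRUE), collapse = ""))
    if (grepl("[A-Z]", substr(id, 2, 4))) return(id)
  }
}

#' Generate a synthetic PDB identifier lexicon
#'
#' Identifiers are synthetic: random tokens over the real PDB id pattern
#' (digit 1-9 + three alphanumerics with at least one letter), not real
#' accessions.  A real id list can be used instead via
#' \code{\link{readLexicon}}.
#'
#' @param n number of valid ids.
#' @param nBlacklist how many of them go on the false-positive blacklist.
#' @param seed RNG seed.
#' @return an \linkS4class{IdLexicon}.
#' @export
generateLexicon <- function(n = 150, nBlacklist = 15, seed = 1) {
  stopifnot(nBlacklist <= n)
  .withSeed(seed, {
    ids <- character(0)
    while (length(ids) < n) ids <- unique(c(ids, .randomPdbId()))
    ids <- sort(ids[seq_len(n)])
    IdLexicon(ids, blacklist = sort(sample(ids, nBlacklist)))
  })
}

#' Specification of a synthetic corpus
#'
#' Defines the study conditions for one generated corpus: how many articles,
#' how many planted identifier mentions per article, and the per-article
#' decoy load (year tokens, pattern-conformant non-lexicon tokens, cue-less
#' blacklisted ids).  Planted mentions of blacklisted ids always carry a cue
#' term (the "survives stricter criteria" direction); cue-less blacklisted
#' plants are decoys (the "filtered" direction).
#'
#' @param nArticles number of articles.
#' @param idsPerArticle integer range (length 2) of planted mentions per
#'   article, sampled uniformly; ids drawn from the lexicon with
#'   replacement, so repeat mentions occur.
#' @param decoyYears,decoyFakeIds,decoyCuelessBlacklist integer ranges
#'   (length 2) of per-article decoy counts.
#' @param termsPerArticle integer range of planted ontology terms per
#'   article (used only when \code{termList} is supplied to
#'   \code{\link{generateCorpus}}).
#' @param captionRate probability that a planted mention lands in a figure
#'   caption rather than a body paragraph.
#' @param seed RNG seed; generation is a pure function of (spec, seed).
#' @return a list of class \code{PlantSpec}.
#' @export
plantSpec <- function(nArticles = 100, idsPerArticle = c(2, 4),
                      decoyYears = c(0, 1), decoyFakeIds = c(0, 1),
                      decoyCuelessBlacklist = c(0, 1),
                      termsPerArticle = c(0, 2), captionRate = 0.25,
                      seed = 1) {
  ranges <- list(idsPerArticle = idsPerArticle, decoyYears = decoyYears,
                 decoyFakeIds = decoyFakeIds,
                 decoyCuelessBlacklist = decoyCuelessBlacklist,
                 termsPerArticle = termsPerArticle)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || any(r < 0) || r[1] > r[2])
      stop("configuration error: ", nm, " must be a non-negative range")
  }
  if (nArticles < 0)
    stop("configuration error: nArticles must be >= 0")
  structure(c(ranges, list(nArticles = nArticles, captionRate = captionRate,
                           seed = seed)),
            class = "PlantSpec")
}

.sampleRange <- function(r) {
  if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1)
}

# One planted sentence.  Returns text plus 0-based half-open offsets of the
# planted token within it.
.plantSentence <- function(token, preExtra = character()) {
  pre <- paste(c(.fillerWords(2), preExtra), collapse = " ")
  post <- paste(.fillerWords(4), collapse = " ")
  list(text = paste(pre, token, post),
       start = nchar(pre) + 1L,
       end = nchar(pre) + 1L + nchar(token))
}

.xmlParagraph <- function(text, italicize = FALSE) {
  esc <- .xmlEscape(text)
  if (italicize) {
    words <- strsplit(esc, " ", fixed = TRUE)[[1]]
    if (length(words) >= 2L)
      words[2] <- paste0("<italic>", words[2], "</italic>")
    esc <- paste(words, collapse = " ")
  }
  esc
}

#' Generate a synthetic JATS corpus with a ground-truth manifest
#'
#' Emits well-formed JATS articles whose planted identifier mentions, decoy
#' tokens and planted ontology terms are recorded in a machine-readable
#' manifest.  Manifest offsets re-locate exactly in the parsed unit texts
#' (generated text is already whitespace-normalised).  Generation is
#' deterministic per (spec, lexicon, termList, seed).
#'
#' @param spec a \code{\link{plantSpec}}.
#' @param lexicon an \linkS4class{IdLexicon} supplying valid and blacklisted
#'   ids.  Mentions are planted from its valid ids; cue-less blacklist
#'   decoys need a non-empty blacklist.
#' @param termList optional data.frame with columns \code{term_id},
#'   \code{surface} (e.g. from \code{\link{generateOBO}}'s manifest) from
#'   which ontology terms are planted.
#' @param dir optional directory; when given, one \code{<pmcid>.xml} file is
#'   written per article.
#' @return list with \code{xml} (named character vector of article XML,
#'   keyed by PMC id) and \code{manifest}, itself a list of data.frames:
#'   \code{articles} (unit counts per article), \code{units} (every unit's
#'   expected plain text), \code{mentions} (planted true mentions with
#'   offsets, blacklist status and cue status), \code{decoys} (planted
#'   decoy tokens with their type), \code{terms} (planted ontology terms
#'   with offsets).
#' @export
generateCorpus <- function(spec, lexicon, termList = NULL, dir = NULL) {
  stopifnot(inherits(spec, "PlantSpec"), is(lexicon, "IdLexicon"))
  if (spec$idsPerArticle[2] > length(validIds(lexicon)))
    stop("configuration error: idsPerArticle exceeds the lexicon size")
  if (spec$decoyCuelessBlacklist[2] > 0 && !length(idBlacklist(lexicon)))
    stop("configuration error: cue-less blacklist decoys need a blacklist")

  .withSeed(spec$seed, {
    xmls <- character(0)
    mentions <- list(); decoys <- list(); terms <- list()
    unitRows <- list(); artRows <- list()

    for (ai in seq_len(spec$nArticles)) {
      pmc <- as.character(100000L + ai)
      nMent <- .sampleRange(spec$idsPerArticle)
      mentIds <- if (nMent) sample(validIds(lexicon), nMent, replace = TRUE)
                 else character()
      nYear <- .sampleRange(spec$decoyYears)
      nFake <- .sampleRange(spec$decoyFakeIds)
      nCueless <- .sampleRange(spec$decoyCuelessBlacklist)
      nTerm <- if (is.null(termList)) 0L
               else .sampleRange(spec$termsPerArticle)

      plants <- list()
      for (id in mentIds) {
        bl <- id %in% idBlacklist(lexicon)
        s <- if (bl) .plantSentence(id, c("the", "PDB", "entry"))
             else .plantSentence(id, "entry")
        plants[[length(plants) + 1L]] <- list(
          what = "mention", token = id, sent = s, blacklisted = bl,
          caption = runif(1) < spec$captionRate)
      }
      for (k in seq_len(nYear)) {
        yr <- as.character(sample(1987:2024, 1))
        plants[[length(plants) + 1L]] <- list(
          what = "decoy_year", token = yr,
          sent = .plantSentence(yr, "in"), caption = FALSE)
      }
      for (k in seq_len(nFake)) {
        repeat {
          tok <- .randomPdbId()
          if (!(tok %in% validIds(lexicon))) break
        }
        plants[[length(plants) + 1L]] <- list(
          what = "decoy_fake_id", token = tok,
          sent = .plantSentence(tok, "lot"), caption = FALSE)
      }
      for (k in seq_len(nCueless)) {
        id <- sample(idBlacklist(lexicon), 1)
        pre <- paste(c(.fillerWords(2), "the"), collapse = " ")
        txt <- paste(pre, id, "software package",
                     paste(.fillerWords(2), collapse = " "))
        plants[[length(plants) + 1L]] <- list(
          what = "decoy_cueless_blacklist", token = id,
          sent = list(text = txt, start = nchar(pre) + 1L,
                      end = nchar(pre) + 1L + nchar(id)),
          caption = FALSE)
      }
      if (nTerm > 0L) {
        rows <- termList[sample(nrow(termList), nTerm, replace = TRUE), ,
                         drop = FALSE]
        for (k in seq_len(nrow(rows))) {
          plants[[length(plants) + 1L]] <- list(
            what = "term", token = rows$surface[k],
            term_id = rows$term_id[k],
            sent = .plantSentence(rows$surface[k]), caption = FALSE)
        }
      }

      isCap <- vapply(plants, function(p) isTRUE(p$caption), logical(1))
      bodyPlants <- plants[!isCap]
      capPlants <- plants[isCap]
      # one plain filler paragraph per article, shuffled in with the plants
      fillerPara <- list(what = "filler", sent = list(
        text = paste(.fillerWords(9), collapse = " "), start = NA, end = NA))
      bodyPlants <- c(bodyPlants, list(fillerPara))
      bodyPlants <- bodyPlants[sample(length(bodyPlants))]

      title <- paste(.fillerWords(5), collapse = " ")
      abstract <- paste(.fillerWords(10), collapse = " ")

      record <- function(p, unitId, kind) {
        s <- p$sent
        if (p$what == "mention") {
          mentions[[length(mentions) + 1L]] <<- data.frame(
            pmc_id = pmc, pdb_id = p$token, unit_id = unitId,
            unit_kind = kind, start = s$start, end = s$end,
            blacklisted = p$blacklisted, has_cue = p$blacklisted,
            stringsAsFactors = FALSE)
        } else if (p$what == "term") {
          terms[[length(terms) + 1L]] <<- data.frame(
            pmc_id = pmc, term_id = p$term_id, surface = p$token,
            unit_id = unitId, start = s$start, end = s$end,
            stringsAsFactors = FALSE)
        } else if (p$what != "filler") {
          decoys[[length(decoys) + 1L]] <<- data.frame(
            pmc_id = pmc, type = sub("^decoy_", "", p$what),
            token = p$token, unit_id = unitId, start = s$start,
            end = s$end, stringsAsFactors = FALSE)
        }
      }

      bodyXml <- character(); bodyTexts <- character()
      for (bi in seq_along(bodyPlants)) {
        p <- bodyPlants[[bi]]
        unitId <- paste0("p-", bi)
        record(p, unitId, "body_para")
        bodyTexts <- c(bodyTexts, p$sent$text)
        bodyXml <- c(bodyXml, paste0(
          "<p>", .xmlParagraph(p$sent$text,
                               italicize = p$what == "filler"), "</p>"))
      }

      figXml <- character(); capTexts <- character(); figIds <- character()
      for (fi in seq_along(capPlants)) {
        p <- capPlants[[fi]]
        figId <- paste0("f", fi)
        figIds <- c(figIds, figId)
        unitId <- paste0("cap-", figId)
        record(p, unitId, "caption")
        capTexts <- c(capTexts, p$sent$text)
        figXml <- c(figXml, paste0(
          '<fig id="', figId, '"><label>Figure ', fi, "</label><caption><p>",
          .xmlParagraph(p$sent$text), "</p></caption>",
          '<graphic xlink:href="', figId, '.png"/></fig>'))
      }

      xml <- paste0(
        '<?xml version="1.0" encoding="UTF-8"?>\n',
        '<article xmlns:xlink="http://www.w3.org/1999/xlink">',
        "<front><article-meta>",
        '<article-id pub-id-type="pmc">', pmc, "</article-id>",
        "<title-group><article-title>", .xmlEscape(title),
        "</article-title></title-group>",
        "<abstract><p>",
        .xmlParagraph(abstract, italicize = ai %% 3L == 0L),
        "</p></abstract>",
        "<permissions><copyright-statement>",
        "Synthetic open-access article; redistribution permitted.",
        "</copyright-statement></permissions>",
        "</article-meta></front>",
        "<body><sec><title>Results</title>",
        paste(bodyXml, collapse = ""),
        "</sec>",
        paste(figXml, collapse = ""),
        "</body></article>")
      xmls[pmc] <- xml

      artRows[[ai]] <- data.frame(
        pmc_id = pmc, n_abstract = 1L, n_body = length(bodyPlants),
        n_figures = length(capPlants), stringsAsFactors = FALSE)
      unitRows[[ai]] <- data.frame(
        pmc_id = pmc,
        unit_id = c("title", "abs-1", paste0("p-", seq_along(bodyTexts)),
                    if (length(figIds)) paste0("cap-", figIds)),
        kind = c("title", "abstract_para",
                 rep("body_para", length(bodyTexts)),
                 rep("caption", length(capTexts))),
        text = c(title, abstract, bodyTexts, capTexts),
        stringsAsFactors = FALSE)
    }

    bindOr <- function(lst, proto) {
      if (length(lst)) {
        out <- do.call(rbind, lst); rownames(out) <- NULL; out
      } else proto
    }
    manifest <- list(
      articles = bindOr(artRows, data.frame(
        pmc_id = character(), n_abstract = integer(), n_body = integer(),
        n_figures = integer(), stringsAsFactors = FALSE)),
      units = bindOr(unitRows, data.frame(
        pmc_id = character(), unit_id = character(), kind = character(),
        text = character(), stringsAsFactors = FALSE)),
      mentions = bindOr(mentions, data.frame(
        pmc_id = character(), pdb_id = character(), unit_id = character(),
        unit_kind = character(), start = integer(), end = integer(),
        blacklisted = logical(), has_cue = logical(),
        stringsAsFactors = FALSE)),
      decoys = bindOr(decoys, data.frame(
        pmc_id = character(), type = character(), token = character(),
        unit_id = character(), start = integer(), end = integer(),
        stringsAsFactors = FALSE)),
      terms = bindOr(terms, data.frame(
        pmc_id = character(), term_id = character(), surface = character(),
        unit_id = character(), start = integer(), end = integer(),
        stringsAsFactors = FALSE))
    )

    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      for (pmc in names(xmls))
        writeLines(xmls[[pmc]], file.path(dir, paste0(pmc, ".xml")),
                   useBytes = TRUE)
      jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                           dataframe = "rows", auto_unbox = TRUE,
                           digits = NA)
    }
    list(xml = xmls, manifest = manifest)
  })
}

#' Generate a synthetic OBO 1.2 ontology with a term manifest
#'
#' Term names are 1-3 words; multi-word names are deliberately nested inside
#' longer names (e.g. "zinc", "zinc finger", "zinc finger domain") to
#' exercise the longest-possible-match rule.  A fraction of terms carry one
#' EXACT synonym; a few extra stanzas are obsolete (skipped by
#' \code{\link{loadOBO}}, listed separately in the manifest).
#'
#' @param nTerms number of active terms.
#' @param synonymRate fraction of terms given an EXACT synonym.
#' @param seed RNG seed.
#' @param nObsolete number of additional obsolete stanzas.
#' @return list with \code{obo} (the OBO text) and \code{manifest}, a
#'   data.frame with columns \code{term_id}, \code{name}, \code{synonym}
#'   (NA when none), \code{obsolete}.
#' @export
generateOBO <- function(nTerms = 500, synonymRate = 0.3, seed = 1,
                        nObsolete = 3) {
  stopifnot(nTerms >= 0, synonymRate >= 0, synonymRate <= 1)
  .withSeed(seed, {
    used <- character(0)
    names_ <- character(0)
    attempts <- 0L
    while (length(names_) < nTerms) {
      attempts <- attempts + 1L
      if (attempts > 50L * nTerms + 1000L)
        stop("configuration error: term name space exhausted; lower nTerms")
      len <- sample(1:3, 1, prob = c(0.2, 0.45, 0.35))
      nm <- paste(sample(.termVocab, len), collapse = " ")
      if (nm %in% used) next
      used <- c(used, nm); names_ <- c(names_, nm)
      # nest: also add the token-prefix of a multi-word name when room allows
      if (len > 1L && length(names_) < nTerms && runif(1) < 0.4) {
        pre <- paste(strsplit(nm, " ")[[1]][seq_len(len - 1L)],
                     collapse = " ")
        if (!(pre %in% used)) {
          used <- c(used, pre); names_ <- c(names_, pre)
        }
      }
    }
    ids <- sprintf("SYN:%07d", seq_along(names_))
    syns <- rep(NA_character_, length(names_))
    for (i in seq_along(names_)) {
      if (runif(1) < synonymRate) {
        # 2- or 3-word synonyms over the synonym vocabulary; bail out if the
        # combination space is exhausted rather than spin forever
        sy <- NA_character_
        for (attempt in 1:200) {
          cand <- paste(sample(.synVocab, sample(2:3, 1)), collapse = " ")
          if (!(cand %in% used)) { used <- c(used, cand); sy <- cand; break }
        }
        if (is.na(sy))
          stop("configuration error: synonym space exhausted; ",
               "lower nTerms or synonymRate")
        syns[i] <- sy
      }
    }
    obsNames <- character(0)
    while (length(obsNames) < nObsolete) {
      nm <- paste(sample(.termVocab, 3), collapse = " ")
      if (!(nm %in% used)) { used <- c(used, nm); obsNames <- c(obsNames, nm) }
    }
    obsIds <- sprintf("SYN:%07d", length(names_) + seq_along(obsNames))

    stanza <- function(id, nm, syn = NA, obsolete = FALSE) {
      c("", "[Term]", paste0("id: ", id), paste0("name: ", nm),
        if (!is.na(syn)) paste0('synonym: "', syn, '" EXACT []'),
        if (obsolete) "is_obsolete: true")
    }
    lines <- c("format-version: 1.2", "ontology: synthetic")
    for (i in seq_along(names_))
      lines <- c(lines, stanza(ids[i], names_[i], syns[i]))
    for (i in seq_along(obsNames))
      lines <- c(lines, stanza(obsIds[i], obsNames[i], obsolete = TRUE))

    manifest <- data.frame(
      term_id = c(ids, obsIds), name = c(names_, obsNames),
      synonym = c(syns, rep(NA_character_, length(obsNames))),
      obsolete = c(rep(FALSE, length(names_)),
                   rep(TRUE, length(obsNames))),
      stringsAsFactors = FALSE)
    list(obo = paste(lines, collapse = "\n"), manifest = manifest)
  })
}

#' Generate related chain sequences in FASTA with an identity manifest
#'
#' All chains derive from one random ancestor of the given length: the first
#' chain of the first entry is the ancestor itself; every other chain is an
#' independent point-mutant (Binomial(length, mutationRate) substitutions at
#' distinct positions, each to a different residue).  Expected identity of
#' any mutant to the ancestor is 100 x (1 - mutationRate) under gapless
#' alignment.  Entry ids are synthetic.
#'
#' @param nEntries number of entries (synthetic PDB ids).
#' @param chainsPerEntry chains per entry.
#' @param mutationRate per-position substitution probability in [0, 1].
#' @param seed RNG seed.
#' @param length chain length.
#' @return list with \code{fasta} (text, headers \code{PDBID_CHAIN}),
#'   \code{chains} (named list pdb id -> named chain vector),
#'   \code{manifest} (data.frame \code{pdb_id}, \code{chain},
#'   \code{n_mutations}) and \code{ancestor}.
#' @export
generateChainFasta <- function(nEntries = 6, chainsPerEntry = 2,
                               mutationRate = 0.05, seed = 1, length = 200) {
  stopifnot(mutationRate >= 0, mutationRate <= 1, nEntries >= 0)
  aa <- setdiff(.aaAlphabet, "X")
  .withSeed(seed, {
    anc <- sample(aa, length, replace = TRUE)
    ids <- character(0)
    while (base::length(ids) < nEntries)
      ids <- unique(c(ids, .randomPdbId()))
    ids <- sort(ids[seq_len(nEntries)])
    chainNames <- LETTERS[seq_len(chainsPerEntry)]
    chains <- list(); rows <- list(); fasta <- character(0)
    for (ei in seq_along(ids)) {
      cs <- character(0)
      for (ci in seq_along(chainNames)) {
        if (ei == 1L && ci == 1L) {
          s <- anc; nMut <- 0L
        } else {
          s <- anc
          nMut <- rbinom(1, length, mutationRate)
          if (nMut > 0L) {
            pos <- sample(length, nMut)
            for (p in pos) s[p] <- sample(setdiff(aa, s[p]), 1)
          }
        }
        seqStr <- paste(s, collapse = "")
        cs[chainNames[ci]] <- seqStr
        rows[[base::length(rows) + 1L]] <- data.frame(
          pdb_id = ids[ei], chain = chainNames[ci], n_mutations = nMut,
          stringsAsFactors = FALSE)
        fasta <- c(fasta, paste0(">", ids[ei], "_", chainNames[ci]),
                   gsub("(.{60})", "\\1\n", seqStr))
      }
      chains[[ids[ei]]] <- cs
    }
    manifest <- if (base::length(rows)) do.call(rbind, rows) else
      data.frame(pdb_id = character(), chain = character(),
                 n_mutations = integer(), stringsAsFactors = FALSE)
    rownames(manifest) <- NULL
    list(fasta = paste(fasta, collapse = "\n"), chains = chains,
         manifest = manifest, ancestor = paste(anc, collapse = ""))
  })
}
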