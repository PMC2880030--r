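#' @include jats.R
NULL

# Canonical surface form: lowercased alphanumeric tokens joined by single
# spaces.  Both dictionary entries and text spans pass through this, so
# "Zinc-Finger" in text matches the entry "zinc finger".
.normSurface <- function(x) {
  toks <- regmatches(x, gregexpr("[A-Za-z0-9]+", x))[[1]]
  paste(tolower(toks), collapse = " ")
}

.tokenCount <- function(x) {
  length(regmatches(x, gregexpr("[A-Za-z0-9]+", x))[[1]])
}

#' TermDictionary: an ontology's surface forms for dictionary tagging
#'
#' Maps normalised surface forms (term names and EXACT synonyms) to term
#' identifiers.  BROAD/NARROW/RELATED synonyms are excluded to control false
#' positives; obsolete terms are skipped.
#'
#' @slot ontologyName name of the source ontology.
#' @slot entries data.frame with columns \code{surface} (normalised, unique),
#'   \code{term_id}, \code{name} (the term's preferred name),
#'   \code{n_tokens}.
#' @slot maxTermTokens token count of the longest entry.
#' @exportClass TermDictionary
setClass("TermDictionary",
  representation(ontologyName = "character", entries = "data.frame",
                 maxTermTokens = "integer")
)

setValidity("TermDictionary", function(object) {
  msgs <- character()
  e <- object@entries
  if (!all(c("surface", "term_id", "name", "n_tokens") %in% names(e)))
    msgs <- c(msgs, "entries needs columns surface, term_id, name, n_tokens")
  else {
    if (any(!nzchar(e$surface)))
      msgs <- c(msgs, "no entry surface form may be empty")
    if (anyDuplicated(e$surface))
      msgs <- c(msgs, "surface forms must be unique within a dictionary")
    expected <- if (nrow(e)) max(e$n_tokens) else 0L
    if (object@maxTermTokens != expected)
      msgs <- c(msgs, "maxTermTokens must equal the longest entry's tokens")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TermDictionary", function(object) {
  cat("TermDictionary '", object@ontologyName, "': ",
      nrow(object@entries), " surface forms, longest ",
      object@maxTermTokens, " tokens\n", sep = "")
})

#' Construct a term dictionary from surface forms
#'
#' When two entries normalise to the same surface form, the one with the
#' lexicographically smallest term id is kept (a deterministic tie-break;
#' ontologies occasionally duplicate synonyms).
#'
#' @param surfaces character vector of names/synonyms (raw text).
#' @param termIds parallel vector of term identifiers.
#' @param names parallel vector of preferred names (defaults to surfaces).
#' @param ontologyName label for the ontology.
#' @return a \linkS4class{TermDictionary}.
#' @export
TermDictionary <- function(surfaces, termIds, names = surfaces,
                           ontologyName = "ontology") {
  norm <- vapply(surfaces, .normSurface, character(1), USE.NAMES = FALSE)
  keep <- nzchar(norm)
  e <- data.frame(surface = norm[keep], term_id = termIds[keep],
                  name = names[keep], stringsAsFactors = FALSE)
  e <- e[order(e$surface, e$term_id), , drop = FALSE]
  e <- e[!duplicated(e$surface), , drop = FALSE]
  e$n_tokens <- vapply(e$surface, .tokenCount, integer(1), USE.NAMES = FALSE)
  rownames(e) <- NULL
  new("TermDictionary", ontologyName = ontologyName, entries = e,
      maxTermTokens = if (nrow(e)) max(e$n_tokens) else 0L)
}

#' @rdname TermDictionary
#' @param x a TermDictionary.
#' @export
setGeneric("dictionaryEntries", function(x) standardGeneric("dictionaryEntries"))

#' @rdname TermDictionary
setMethod("dictionaryEntries", "TermDictionary", function(x) x@entries)

#' @rdname TermDictionary
#' @export
setGeneric("ontologyName", function(x) standardGeneric("ontologyName"))

#' @rdname TermDictionary
setMethod("ontologyName", "TermDictionary", function(x) x@ontologyName)

#' Load an OBO 1.2 ontology into a term dictionary
#'
#' One dictionary entry is created per term name and per EXACT synonym;
#' obsolete terms are skipped.  Surface forms are normalised (lowercased,
#' whitespace collapsed).
#'
#' @param x path to an OBO file, or a single string of OBO text.
#' @param ontologyName label; defaults to the file's \code{ontology:} header
#'   field when present, else "ontology".
#' @return a \linkS4class{TermDictionary}.
#' @export
loadOBO <- function(x, ontologyName = NULL) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x, warn = FALSE)
  else
    strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE)[[1]]

  if (is.null(ontologyName)) {
    h <- grep("^ontology:", lines, value = TRUE)
    ontologyName <- if (length(h)) .squish(sub("^ontology:", "", h[1]))
                    else "ontology"
  }

  stanzaStarts <- grep("^\\[", lines)
  surfaces <- character(); ids <- character(); prefNames <- character()
  for (k in seq_along(stanzaStarts)) {
    s <- stanzaStarts[k]
    if (lines[s] != "[Term]") next
    e <- if (k < length(stanzaStarts)) stanzaStarts[k + 1] - 1L
         else length(lines)
    block <- lines[(s + 1):e]
    getField <- function(key) {
      v <- grep(paste0("^", key, ":"), block, value = TRUE)
      .squish(sub(paste0("^", key, ":"), "", v))
    }
    id <- getField("id")
    nm <- getField("name")
    if (length(id) != 1L || length(nm) != 1L)
      stop("unparseable OBO stanza starting at line ", s,
           ": a [Term] needs exactly one id and one name")
    obs <- getField("is_obsolete")
    if (length(obs) && tolower(obs[1]) == "true") next
    synLines <- grep("^synonym:", block, value = TRUE)
    exacts <- character()
    for (sl in synLines) {
      m <- regmatches(sl, regexec('^synonym:\\s*"([^"]*)"\\s+(\\w+)', sl))[[1]]
      if (length(m) == 3L && m[3] == "EXACT") exacts <- c(exacts, m[2])
    }
    surf <- c(nm, exacts)
    surfaces <- c(surfaces, surf)
    ids <- c(ids, rep(id, length(surf)))
    prefNames <- c(prefNames, rep(nm, length(surf)))
  }
  TermDictionary(surfaces, ids, prefNames, ontologyName = ontologyName)
}

.emptyTermMatches <- function() {
  data.frame(term_id = character(), ontology = character(),
             start = integer(), end = integer(),
             matched_text = character(), stringsAsFactors = FALSE)
}

#' Tag ontology terms in text with the longest-possible-match rule
#'
#' Scans left to right over token boundaries.  At each position the longest
#' dictionary match (in tokens; ties by character length, then lexicographic
#' term id) is emitted and the scan resumes after it, so matches within one
#' dictionary never overlap.  Matching is case-insensitive and
#' token-boundary aligned: "cat" never matches inside "catalysis".
#'
#' @param text a single string of plain text.
#' @param dictionary a \linkS4class{TermDictionary}.
#' @return data.frame with columns \code{term_id}, \code{ontology},
#'   \code{start}, \code{end} (0-based half-open), \code{matched_text}.
#' @examples
#' d <- TermDictionary(c("zinc", "zinc finger"), c("T:2", "T:1"))
#' tagTerms("a zinc finger motif", d)  # emits only "zinc finger"
#' @export
tagTerms <- function(text, dictionary) {
  stopifnot(is.character(text), length(text) == 1L,
            is(dictionary, "TermDictionary"))
  e <- dictionary@entries
  if (nrow(e) == 0L || !nzchar(text)) return(.emptyTermMatches())
  lookup <- e$term_id
  names(lookup) <- e$surface

  m <- gregexpr("[A-Za-z0-9]+", text)[[1]]
  if (m[1] == -1L) return(.emptyTermMatches())
  tokStart <- as.integer(m)
  tokEnd <- tokStart + attr(m, "match.length") - 1L
  toks <- tolower(substring(text, tokStart, tokEnd))
  n <- length(toks)
  maxLen <- dictionary@maxTermTokens

  res <- list(); ri <- 0L; i <- 1L
  while (i <= n) {
    hit <- 0L
    for (len in seq(min(maxLen, n - i + 1L), 1L)) {
      key <- paste(toks[i:(i + len - 1L)], collapse = " ")
      tid <- lookup[key]
      if (!is.na(tid)) { hit <- len; hitId <- unname(tid); break }
    }
    if (hit > 0L) {
      ri <- ri + 1L
      res[[ri]] <- list(term_id = hitId,
                        start = tokStart[i] - 1L,
                        end = tokEnd[i + hit - 1L])
      i <- i + hit
    } else {
      i <- i + 1L
    }
  }
  if (ri == 0L) return(.emptyTermMatches())
  starts <- vapply(res, function(r) r$start, integer(1))
  ends <- vapply(res, function(r) r$end, integer(1))
  data.frame(term_id = vapply(res, function(r) r$term_id, character(1)),
             ontology = dictionary@ontologyName,
             start = starts, end = ends,
             matched_text = substring(text, starts + 1L, ends),
             stringsAsFactors = FALSE)
}

#' Tag an article's units against one or more ontologies
#'
#' Each dictionary is applied independently per unit; when several
#' ontologies match the same span, one TermMatch per ontology is kept (spans
#' may coincide across ontologies but never overlap within one ontology).
#'
#' @param article an \linkS4class{Article}.
#' @param dictionaries list of \linkS4class{TermDictionary} objects.
#' @return named list, one entry per unit id, each a data.frame as returned
#'   by \code{\link{tagTerms}} (rows from all ontologies combined).
#' @export
tagArticle <- function(article, dictionaries) {
  if (is(dictionaries, "TermDictionary")) dictionaries <- list(dictionaries)
  u <- textUnits(article)
  out <- vector("list", nrow(u))
  names(out) <- u$unit_id
  for (i in seq_len(nrow(u))) {
    per <- lapply(dictionaries, function(d) tagTerms(u$text[i], d))
    df <- do.call(rbind, per)
    rownames(df) <- NULL
    out[[i]] <- df
  }
  out
}
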