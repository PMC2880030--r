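#' @include jats.R
NULL

.defaultCueTerms <- function() {
  c("PDB", "Protein Data Bank", "accession", "structure", "crystal structure")
}

.pdbIdPattern <- "^[1-9][A-Za-z0-9]{3}$"

#' IdLexicon: the valid-identifier universe and its false-positive blacklist
#'
#' PDB accession codes are four characters (a digit 1-9 followed by three
#' alphanumerics) and therefore collide with ordinary vocabulary: "3DNA", a
#' valid entry, is also the name of a software package and of a wet-lab kit.
#' Identifiers known to produce such false positives go on the blacklist and
#' are accepted only when a contextual cue term (e.g. "PDB", "crystal
#' structure") occurs in the same text unit.
#'
#' @slot validIds uppercase 4-character identifiers considered valid.
#' @slot blacklist subset of validIds requiring a contextual cue.
#' @slot cueTerms cue keywords, matched case-insensitively within the unit.
#' @exportClass IdLexicon
setClass("IdLexicon",
  representation(validIds = "character", blacklist = "character",
                 cueTerms = "character")
)

setValidity("IdLexicon", function(object) {
  msgs <- character()
  bad <- object@validIds[!grepl(.pdbIdPattern, object@validIds)]
  if (length(bad))
    msgs <- c(msgs, paste0("invalid PDB id(s) in lexicon: ",
                           paste(head(bad, 5), collapse = ", ")))
  if (!all(grepl("[A-Za-z]", object@validIds)) && length(object@validIds))
    msgs <- c(msgs, "every valid id needs at least one letter")
  if (!all(object@blacklist %in% object@validIds))
    msgs <- c(msgs, "blacklist must be a subset of validIds")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "IdLexicon", function(object) {
  cat("IdLexicon with ", length(object@validIds), " valid ids, ",
      length(object@blacklist), " blacklisted, ",
      length(object@cueTerms), " cue terms\n", sep = "")
})

#' Construct an identifier lexicon
#'
#' @param validIds character vector of 4-character PDB ids (any case).
#' @param blacklist ids requiring stricter contextual criteria.
#' @param cueTerms context keywords accepted as evidence for blacklisted ids.
#' @return an \linkS4class{IdLexicon}.
#' @examples
#' lex <- IdLexicon(c("1HIV", "3BY7", "3DNA"), blacklist = "3DNA")
#' lex
#' @export
IdLexicon <- function(validIds, blacklist = character(),
                      cueTerms = .defaultCueTerms()) {
  new("IdLexicon", validIds = toupper(unique(validIds)),
      blacklist = toupper(unique(blacklist)), cueTerms = cueTerms)
}

#' @rdname IdLexicon
#' @param x an IdLexicon.
#' @export
setGeneric("validIds", function(x) standardGeneric("validIds"))

#' @rdname IdLexicon
setMethod("validIds", "IdLexicon", function(x) x@validIds)

#' @rdname IdLexicon
#' @export
setGeneric("idBlacklist", function(x) standardGeneric("idBlacklist"))

#' @rdname IdLexicon
setMethod("idBlacklist", "IdLexicon", function(x) x@blacklist)

#' @rdname IdLexicon
#' @export
setGeneric("cueTerms", function(x) standardGeneric("cueTerms"))

#' @rdname IdLexicon
setMethod("cueTerms", "IdLexicon", function(x) x@cueTerms)

#' Read an identifier lexicon from plain-text files
#'
#' Each file lists one identifier per line; "#" starts a comment; matching is
#' case-insensitive.  Cue terms may be given in a file with one term per line
#' (same comment convention).
#'
#' @param path file of valid ids.
#' @param blacklistPath optional file of blacklisted ids.
#' @param cuePath optional file of cue terms; default cue set otherwise.
#' @return an \linkS4class{IdLexicon}.
#' @export
readLexicon <- function(path, blacklistPath = NULL, cuePath = NULL) {
  readIds <- function(p) {
    x <- readLines(p, warn = FALSE)
    x <- .squish(sub("#.*$", "", x))
    x[nzchar(x)]
  }
  IdLexicon(readIds(path),
            blacklist = if (is.null(blacklistPath)) character()
                        else readIds(blacklistPath),
            cueTerms = if (is.null(cuePath)) .defaultCueTerms()
                       else readIds(cuePath))
}

.emptyMentions <- function() {
  data.frame(pdb_id = character(), pmc_id = character(),
             unit_id = character(), unit_kind = character(),
             start = integer(), end = integer(),
             context = character(), cue_found = logical(),
             stringsAsFactors = FALSE)
}

#' Find candidate PDB identifiers in plain text
#'
#' A candidate is a maximal word-bounded token of exactly four characters
#' whose first character is a digit 1-9 and whose remaining three characters
#' are alphanumeric with at least one letter.  All-digit tokens (years) are
#' never candidates.  A candidate must not be adjacent to an alphanumeric
#' character; hyphen and underscore count as boundaries, so "PDB:1HIV" and
#' "(1HIV)" match.
#'
#' @param text a single string of plain text.
#' @return data.frame with columns \code{token}, \code{start}, \code{end};
#'   offsets are 0-based half-open into \code{text}.
#' @examples
#' findCandidates("the PDB ID 3BY7 was cited")
#' findCandidates("published in 2009 and 2010")  # years excluded
#' @export
findCandidates <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(token = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  m <- gregexpr("(?<![A-Za-z0-9])[1-9][A-Za-z0-9]{3}(?![A-Za-z0-9])",
                text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  tokens <- substring(text, starts, starts + 3L)
  keep <- grepl("[A-Za-z]", tokens)
  data.frame(token = tokens[keep], start = starts[keep] - 1L,
             end = starts[keep] + 3L, stringsAsFactors = FALSE)
}

#' Validate candidate tokens against the identifier lexicon
#'
#' Keeps exactly the candidates whose uppercased token is a valid identifier;
#' matching is case-insensitive and the stored \code{pdb_id} is canonical
#' uppercase.
#'
#' @param candidates data.frame from \code{\link{findCandidates}}.
#' @param lexicon an \linkS4class{IdLexicon}; must be non-empty.
#' @param pmcId,unitId,unitKind locators recorded into each mention.
#' @return mention data.frame (see \code{\link{mineArticle}}); \code{context}
#'   and \code{cue_found} are filled by later stages.
#' @export
validateCandidates <- function(candidates, lexicon, pmcId, unitId, unitKind) {
  stopifnot(is(lexicon, "IdLexicon"))
  if (length(validIds(lexicon)) == 0L)
    stop("configuration error: the identifier lexicon is empty")
  if (nrow(candidates) == 0L) return(.emptyMentions())
  up <- toupper(candidates$token)
  keep <- up %in% validIds(lexicon)
  if (!any(keep)) return(.emptyMentions())
  data.frame(pdb_id = up[keep], pmc_id = pmcId, unit_id = unitId,
             unit_kind = unitKind,
             start = candidates$start[keep], end = candidates$end[keep],
             context = NA_character_, cue_found = NA,
             stringsAsFactors = FALSE)
}

.unitHasCue <- function(unitText, lexicon) {
  lt <- tolower(unitText)
  any(vapply(tolower(cueTerms(lexicon)),
             function(cue) grepl(cue, lt, fixed = TRUE), logical(1)))
}

#' Apply the false-positive blacklist with the contextual cue rule
#'
#' A mention of a blacklisted identifier is kept only if a cue term occurs
#' (case-insensitively) anywhere in the same text unit; mentions of
#' non-blacklisted identifiers pass unchanged.  \code{cue_found} is set for
#' every mention.  Each filtered mention is logged at level "info" with its
#' unit id, so false-positive handling is auditable.
#'
#' @param mentions mention data.frame located in \code{unitText}.
#' @param unitText the full text of the containing unit.
#' @param lexicon an \linkS4class{IdLexicon}.
#' @return the surviving mentions.
#' @export
applyBlacklistFilter <- function(mentions, unitText, lexicon) {
  stopifnot(is(lexicon, "IdLexicon"))
  if (nrow(mentions) == 0L) return(mentions)
  cue <- .unitHasCue(unitText, lexicon)
  mentions$cue_found <- cue
  drop <- mentions$pdb_id %in% idBlacklist(lexicon) & !cue
  if (any(drop)) {
    for (i in which(drop))
      .log("info", "blacklist filter dropped ", mentions$pdb_id[i],
           " in unit ", mentions$unit_id[i], " (no cue term)")
  }
  mentions[!drop, , drop = FALSE]
}

#' Extract the display context of a mention
#'
#' The context is the full text of the containing unit: the surrounding
#' paragraph for body or abstract mentions, the article title for title
#' mentions, and the figure legend for mentions inside captions.
#'
#' @param article an \linkS4class{Article}.
#' @param mention one mention row (list or 1-row data.frame) with
#'   \code{unit_id}.
#' @return the context text.
#' @export
extractContext <- function(article, mention) {
  unitId <- mention$unit_id
  u <- textUnits(article)
  i <- match(unitId, u$unit_id)
  if (is.na(i))
    stop("unknown unit_id '", unitId, "' in article ", pmcID(article))
  if (u$kind[i] == "caption") {
    figId <- sub("^cap-", "", unitId)
    figs <- figures(article)
    figs$caption[match(figId, figs$figure_id)]
  } else {
    u$text[i]
  }
}

#' Mine one article for validated PDB identifier mentions
#'
#' Runs candidate detection, lexicon validation, blacklist filtering and
#' context extraction over every text unit in canonical order.  Duplicate
#' mentions of one identifier within a unit are all recorded; deduplication
#' happens at association level.
#'
#' @param article an \linkS4class{Article}.
#' @param lexicon an \linkS4class{IdLexicon}.
#' @return data.frame with one row per mention: \code{pdb_id} (canonical
#'   uppercase), \code{pmc_id}, \code{unit_id}, \code{unit_kind},
#'   \code{start}, \code{end} (0-based half-open offsets into the
#'   whitespace-normalised unit text), \code{context}, \code{cue_found}.
#' @export
mineArticle <- function(article, lexicon) {
  u <- textUnits(article)
  out <- vector("list", nrow(u))
  for (i in seq_len(nrow(u))) {
    cand <- findCandidates(u$text[i])
    if (nrow(cand) == 0L) next
    men <- validateCandidates(cand, lexicon, pmcID(article),
                              u$unit_id[i], u$kind[i])
    men <- applyBlacklistFilter(men, u$text[i], lexicon)
    if (nrow(men)) {
      men$context <- u$text[i]
      out[[i]] <- men
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(.emptyMentions())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mine a corpus of articles
#'
#' @param articles list of \linkS4class{Article} objects (e.g. from
#'   \code{\link{readCorpus}}).
#' @param lexicon an \linkS4class{IdLexicon}.
#' @return corpus-wide mention data.frame (see \code{\link{mineArticle}}).
#' @export
mineCorpus <- function(articles, lexicon) {
  res <- do.call(rbind, lapply(articles, mineArticle, lexicon = lexicon))
  if (is.null(res)) return(.emptyMentions())
  rownames(res) <- NULL
  res
}
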