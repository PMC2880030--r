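#' @include association.R
NULL

#' Article-metadata payloads for all articles mentioning a PDB id
#'
#' Emulates, as files, the web-service response that lists every article
#' containing a given identifier: one payload per article, each restricted
#' to mentions of that id, ordered deterministically by PMC id.  Keys within
#' a payload are sorted so serialisation is byte-stable.
#'
#' @param table an \linkS4class{AssociationTable} built from \code{mentions}.
#' @param articles named list of \linkS4class{Article} objects (by PMC id).
#' @param mentions corpus-wide mention data.frame.
#' @param pdbId target identifier; an unknown id yields an empty list (a
#'   valid but unmentioned structure, not an error).
#' @return list of payloads; each payload is a key-sorted list with fields
#'   \code{abstract}, \code{license_note}, \code{mentions} (list of
#'   \code{context}/\code{pdb_id}/\code{unit_kind}), \code{pmc_id},
#'   \code{title}.
#' @export
exportMetadataForId <- function(table, articles, mentions, pdbId) {
  stopifnot(is(table, "AssociationTable"))
  pdbId <- toupper(pdbId)
  arts <- articlesById(table)[[pdbId]]
  if (is.null(arts)) return(list())
  lapply(sort(arts), function(pmc) {
    art <- articles[[pmc]]
    sel <- mentions[mentions$pmc_id == pmc & mentions$pdb_id == pdbId, ,
                    drop = FALSE]
    list(
      abstract = paste(art@abstract, collapse = " "),
      license_note = art@copyrightNote,
      mentions = lapply(seq_len(nrow(sel)), function(i) list(
        context = sel$context[i],
        pdb_id = sel$pdb_id[i],
        unit_kind = sel$unit_kind[i]
      )),
      pmc_id = pmc,
      title = art@title
    )
  })
}

#' Figure-list payload for one article
#'
#' @param article an \linkS4class{Article}.
#' @return key-sorted list with \code{figures} (document order; each with
#'   \code{caption}, \code{figure_id}, \code{graphic_ref}, \code{label})
#'   and \code{pmc_id}.
#' @export
exportFigures <- function(article) {
  f <- figures(article)
  list(
    figures = lapply(seq_len(nrow(f)), function(i) list(
      caption = f$caption[i],
      figure_id = f$figure_id[i],
      graphic_ref = if (is.na(f$graphic_ref[i])) NULL else f$graphic_ref[i],
      label = f$label[i]
    )),
    pmc_id = pmcID(article)
  )
}

#' Write a payload as deterministic JSON
#'
#' @param payload a payload list (keys already sorted by construction).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writePayload <- function(payload, path) {
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# Resolve span conflicts inside one unit: PDB mentions take precedence over
# term spans; a term overlapping a retained mention is dropped and logged.
# Terms from different ontologies may share a span (emitted as nested
# elements) but partially overlapping terms are resolved first-come by
# (start, -length, ontology).
.resolveSpans <- function(mentions, terms, unitId) {
  spans <- list()
  if (!is.null(mentions) && nrow(mentions)) {
    for (i in seq_len(nrow(mentions)))
      spans[[length(spans) + 1L]] <- list(
        type = "mention", start = mentions$start[i], end = mentions$end[i],
        attrs = c("pdb-id" = mentions$pdb_id[i]))
  }
  taken <- do.call(rbind, lapply(spans, function(s) c(s$start, s$end)))
  if (!is.null(terms) && nrow(terms)) {
    terms <- terms[order(terms$start, -(terms$end - terms$start),
                         terms$ontology), , drop = FALSE]
    kept <- list()
    for (i in seq_len(nrow(terms))) {
      s <- terms$start[i]; e <- terms$end[i]
      clashM <- !is.null(taken) &&
        any(s < taken[, 2] & taken[, 1] < e)
      if (clashM) {
        .log("info", "term ", terms$term_id[i], " overlaps a PDB mention in ",
             unitId, "; term dropped")
        next
      }
      clashT <- FALSE
      for (k in kept) {
        ov <- s < k$end && k$start < e
        samespan <- s == k$start && e == k$end
        if (ov && !samespan) { clashT <- TRUE; break }
      }
      if (clashT) {
        .log("info", "term ", terms$term_id[i],
             " partially overlaps an earlier term in ", unitId, "; dropped")
        next
      }
      k <- list(type = "term", start = s, end = e,
                attrs = c(ontology = terms$ontology[i],
                          "term-id" = terms$term_id[i]))
      kept[[length(kept) + 1L]] <- k
      spans[[length(spans) + 1L]] <- k
    }
  }
  spans
}

.renderUnit <- function(text, spans) {
  if (!length(spans)) return(.xmlEscape(text))
  starts <- vapply(spans, function(s) s$start, numeric(1))
  ends <- vapply(spans, function(s) s$end, numeric(1))
  o <- order(starts, -ends,
             vapply(spans, function(s) paste(s$attrs, collapse = "|"),
                    character(1)))
  spans <- spans[o]; starts <- starts[o]; ends <- ends[o]
  out <- character(); pos <- 0L; i <- 1L
  openTag <- function(s) {
    a <- s$attrs
    paste0("<", s$type, " ",
           paste0(names(a), '="', .xmlEscape(unname(a)), '"',
                  collapse = " "), ">")
  }
  # spans are non-overlapping or exactly coincident (nested) at this point
  while (i <= length(spans)) {
    grp <- which(starts == starts[i] & ends == ends[i])
    s <- starts[i]; e <- ends[i]
    if (s > pos) out <- c(out, .xmlEscape(substr(text, pos + 1L, s)))
    for (g in grp) out <- c(out, openTag(spans[[g]]))
    out <- c(out, .xmlEscape(substr(text, s + 1L, e)))
    for (g in rev(grp)) out <- c(out, paste0("</", spans[[g]]$type, ">"))
    pos <- e
    i <- max(grp) + 1L
  }
  if (pos < nchar(text))
    out <- c(out, .xmlEscape(substr(text, pos + 1L, nchar(text))))
  paste(out, collapse = "")
}

#' Emit annotated article XML with inline mention and term markup
#'
#' Each PDB mention span is wrapped in a \code{<mention pdb-id="...">}
#' element and each ontology term span in a
#' \code{<term ontology="..." term-id="...">} element.  Stripping all
#' annotation elements (e.g. via \code{\link{stripMarkup}}) recovers every
#' unit text byte-identically.  When a term span overlaps a mention span,
#' the mention wins and the term is dropped (logged).
#'
#' @param article an \linkS4class{Article}.
#' @param mentions mention data.frame for this article (may be empty/NULL).
#' @param termMatches per-unit term list from \code{\link{tagArticle}}
#'   (may be NULL).
#' @return a single string of XML.
#' @export
writeMarkup <- function(article, mentions = NULL, termMatches = NULL) {
  u <- textUnits(article)
  out <- c('<?xml version="1.0" encoding="UTF-8"?>',
           paste0('<annotated-article pmc-id="',
                  .xmlEscape(pmcID(article)), '">'))
  for (i in seq_len(nrow(u))) {
    uid <- u$unit_id[i]
    men <- if (is.null(mentions) || nrow(mentions) == 0L) NULL
           else mentions[mentions$unit_id == uid, , drop = FALSE]
    trm <- if (is.null(termMatches)) NULL else termMatches[[uid]]
    spans <- .resolveSpans(men, trm, uid)
    out <- c(out,
             paste0('  <unit id="', .xmlEscape(uid), '" kind="',
                    u$kind[i], '">', .renderUnit(u$text[i], spans),
                    "</unit>"))
  }
  out <- c(out, "</annotated-article>")
  paste(out, collapse = "\n")
}

#' Strip annotation markup, recovering the plain unit texts
#'
#' @param xmlText output of \code{\link{writeMarkup}}.
#' @return named character vector of unit texts, keyed by unit id.
#' @export
stripMarkup <- function(xmlText) {
  doc <- xml2::read_xml(xmlText)
  units <- xml2::xml_find_all(doc, ".//unit")
  stats::setNames(xml2::xml_text(units), xml2::xml_attr(units, "id"))
}
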