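#' @include pdbmine-package.R
NULL

#' Article: structured representation of one JATS full-text document
#'
#' Holds the minable content of one NLM/JATS article: identifier, title,
#' abstract paragraphs, body paragraphs (with their section path), figures
#' with captions, and the copyright note.  Text units are stored in canonical
#' mining order: title, abstract paragraphs, body paragraphs in document
#' order, then figure captions in figure order.
#'
#' @slot pmcID PubMed Central identifier (non-empty).
#' @slot title article title, markup flattened.
#' @slot abstract character vector of abstract paragraphs (may be empty).
#' @slot copyrightNote copyright/license statement, possibly "".
#' @slot units data.frame with columns \code{unit_id}, \code{kind}
#'   (title / abstract_para / body_para / caption), \code{section}
#'   (" / "-joined section titles, "" for front matter), \code{text}.
#' @slot figures data.frame with columns \code{figure_id}, \code{label},
#'   \code{caption}, \code{graphic_ref} (NA when absent).
#' @exportClass Article
setClass("Article",
  representation(
    pmcID = "character",
    title = "character",
    abstract = "character",
    copyrightNote = "character",
    units = "data.frame",
    figures = "data.frame"
  )
)

setValidity("Article", function(object) {
  msgs <- character()
  if (length(object@pmcID) != 1L || !nzchar(object@pmcID))
    msgs <- c(msgs, "pmcID must be a single non-empty string")
  u <- object@units
  need <- c("unit_id", "kind", "section", "text")
  if (!all(need %in% names(u)))
    msgs <- c(msgs, "units must have columns unit_id, kind, section, text")
  else {
    if (anyDuplicated(u$unit_id))
      msgs <- c(msgs, "unit_id values must be unique within an article")
    if (!all(u$kind %in% c("title", "abstract_para", "body_para", "caption")))
      msgs <- c(msgs, "unknown unit kind")
    capIds <- sub("^cap-", "", u$unit_id[u$kind == "caption"])
    if (!all(capIds %in% object@figures$figure_id))
      msgs <- c(msgs, "every caption unit must reference a figure")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "Article", function(object) {
  cat("Article PMC", object@pmcID, "\n",
      "  title:    ", substr(object@title, 1, 60), "\n",
      "  units:    ", nrow(object@units),
      " (", sum(object@units$kind == "body_para"), " body paragraphs)\n",
      "  figures:  ", nrow(object@figures), "\n", sep = "")
})

#' Accessors for Article objects
#'
#' \code{pmcID} returns the PMC identifier, \code{articleTitle} the flattened
#' title, \code{figures} the figure table (columns \code{figure_id},
#' \code{label}, \code{caption}, \code{graphic_ref}).
#'
#' @param x an \linkS4class{Article}.
#' @return a character scalar (\code{pmcID}, \code{articleTitle}) or a
#'   data.frame (\code{figures}).
#' @name article-accessors
#' @export
setGeneric("pmcID", function(x) standardGeneric("pmcID"))

#' @rdname article-accessors
setMethod("pmcID", "Article", function(x) x@pmcID)

#' @rdname article-accessors
#' @export
setGeneric("articleTitle", function(x) standardGeneric("articleTitle"))

#' @rdname article-accessors
setMethod("articleTitle", "Article", function(x) x@title)

#' @rdname article-accessors
#' @export
setGeneric("figures", function(x) standardGeneric("figures"))

#' @rdname article-accessors
setMethod("figures", "Article", function(x) x@figures)

.emptyUnits <- function() {
  data.frame(unit_id = character(), kind = character(),
             section = character(), text = character(),
             stringsAsFactors = FALSE)
}

.emptyFigures <- function() {
  data.frame(figure_id = character(), label = character(),
             caption = character(), graphic_ref = character(),
             stringsAsFactors = FALSE)
}

.nodeText <- function(node) {
  # xml_text flattens inline formatting (italic/bold/sub/sup) and
  # cross-references to their display text; whitespace is then collapsed so
  # offsets are stable across pretty-printed XML
  .squish(xml2::xml_text(node))
}

#' Parse a JATS/NLM full-text article into an Article object
#'
#' Accepts both NLM 2.x and JATS 1.x tag names.  Unrecognised elements are
#' descended into and their text preserved (lenient parsing; PMC content
#' spans DTD generations).  Paragraphs inside figures, tables and reference
#' lists are not text units: figure captions are mined separately and tables
#' and reference lists are deliberately excluded.
#'
#' @param x path to an XML file, or a single string of XML text.
#' @return an \linkS4class{Article}.
#' @examples
#' xml <- paste0(
#'   '<article><front><article-meta>',
#'   '<article-id pub-id-type="pmc">1483839</article-id>',
#'   '<title-group><article-title>A title</article-title></title-group>',
#'   '</article-meta></front>',
#'   '<body><p>Hello</p></body></article>')
#' art <- parseJATS(xml)
#' textUnits(art)
#' @export
parseJATS <- function(x) {
  doc <- xml2::read_xml(x)

  pmc <- xml2::xml_find_first(
    doc,
    paste0(".//front//article-id[@pub-id-type='pmc' or @pub-id-type='pmcid']",
           " | .//article-id[@pub-id-type='pmc' or @pub-id-type='pmcid']"))
  if (inherits(pmc, "xml_missing"))
    stop("no pmc id: article carries no article-id of pub-id-type 'pmc'")
  pmcId <- .squish(xml2::xml_text(pmc))
  if (!nzchar(pmcId))
    stop("no pmc id: empty article-id element")

  titleNode <- xml2::xml_find_first(doc, ".//title-group/article-title")
  title <- if (inherits(titleNode, "xml_missing")) "" else .nodeText(titleNode)

  absParas <- xml2::xml_find_all(doc, ".//front//abstract//p")
  if (length(absParas) == 0L) {
    absNode <- xml2::xml_find_first(doc, ".//front//abstract")
    abstract <- if (inherits(absNode, "xml_missing")) character() else {
      txt <- .nodeText(absNode)
      if (nzchar(txt)) txt else character()
    }
  } else {
    abstract <- vapply(absParas, .nodeText, character(1))
  }

  cpNode <- xml2::xml_find_first(
    doc, ".//front//copyright-statement | .//front//license")
  copyrightNote <- if (inherits(cpNode, "xml_missing")) "" else .nodeText(cpNode)

  bodyParas <- xml2::xml_find_all(
    doc,
    paste0(".//body//p[not(ancestor::fig) and not(ancestor::table-wrap)",
           " and not(ancestor::ref-list) and not(ancestor::caption)",
           " and not(ancestor::boxed-text)]"))
  sectionOf <- function(p) {
    titles <- xml2::xml_find_all(p, "ancestor::sec/title")
    paste(vapply(titles, .nodeText, character(1)), collapse = " / ")
  }

  figNodes <- xml2::xml_find_all(doc, ".//fig")
  figs <- .emptyFigures()
  if (length(figNodes)) {
    ids <- xml2::xml_attr(figNodes, "id")
    ids[is.na(ids)] <- paste0("fig", seq_along(figNodes))[is.na(ids)]
    figs <- data.frame(
      figure_id = ids,
      label = vapply(figNodes, function(f) {
        n <- xml2::xml_find_first(f, "./label")
        if (inherits(n, "xml_missing")) "" else .nodeText(n)
      }, character(1)),
      caption = vapply(figNodes, function(f) {
        n <- xml2::xml_find_first(f, "./caption")
        if (inherits(n, "xml_missing")) "" else .nodeText(n)
      }, character(1)),
      graphic_ref = vapply(figNodes, function(f) {
        n <- xml2::xml_find_first(f, ".//graphic")
        if (inherits(n, "xml_missing")) NA_character_
        else xml2::xml_attr(n, "href")
      }, character(1)),
      stringsAsFactors = FALSE
    )
  }

  units <- rbind(
    data.frame(unit_id = "title", kind = "title", section = "",
               text = title, stringsAsFactors = FALSE),
    if (length(abstract))
      data.frame(unit_id = paste0("abs-", seq_along(abstract)),
                 kind = "abstract_para", section = "",
                 text = abstract, stringsAsFactors = FALSE)
    else .emptyUnits(),
    if (length(bodyParas))
      data.frame(unit_id = paste0("p-", seq_along(bodyParas)),
                 kind = "body_para",
                 section = vapply(bodyParas, sectionOf, character(1)),
                 text = vapply(bodyParas, .nodeText, character(1)),
                 stringsAsFactors = FALSE)
    else .emptyUnits(),
    if (nrow(figs))
      data.frame(unit_id = paste0("cap-", figs$figure_id),
                 kind = "caption", section = "",
                 text = figs$caption, stringsAsFactors = FALSE)
    else .emptyUnits()
  )
  rownames(units) <- NULL

  new("Article", pmcID = pmcId, title = title, abstract = abstract,
      copyrightNote = copyrightNote, units = units, figures = figs)
}

#' Enumerate the minable text units of an article
#'
#' Units are returned in canonical order: title, abstract paragraphs, body
#' paragraphs in document order, then figure captions in figure order.  The
#' total count is \code{1 + n_abstract + n_body + n_figures}.
#'
#' @param x an \linkS4class{Article}.
#' @return data.frame with columns \code{unit_id}, \code{kind},
#'   \code{section}, \code{text}.
#' @export
setGeneric("textUnits", function(x) standardGeneric("textUnits"))

#' @rdname textUnits
setMethod("textUnits", "Article", function(x) x@units)

#' Read a directory of JATS XML files into a list of Articles
#'
#' @param dir directory containing one article per \code{.xml} file.
#' @return named list of \linkS4class{Article} objects, keyed by PMC id.
#' @export
readCorpus <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  arts <- lapply(paths, parseJATS)
  names(arts) <- vapply(arts, pmcID, character(1))
  arts
}
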