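#' @include mine.R
NULL

#' AssociationTable: corpus-level structure-article associations
#'
#' Stores one row per (PDB id, article) pair with the number of mention
#' records supporting it.  The by-id and by-article views offered by the
#' accessors are transposes of each other by construction.
#'
#' @slot assoc data.frame with columns \code{pdb_id}, \code{pmc_id},
#'   \code{mention_count} (>= 1), one row per distinct pair.
#' @exportClass AssociationTable
setClass("AssociationTable", representation(assoc = "data.frame"))

setValidity("AssociationTable", function(object) {
  a <- object@assoc
  msgs <- character()
  if (!all(c("pdb_id", "pmc_id", "mention_count") %in% names(a)))
    msgs <- c(msgs, "assoc needs columns pdb_id, pmc_id, mention_count")
  else {
    if (nrow(a) && any(a$mention_count < 1L))
      msgs <- c(msgs, "mention_count must be >= 1 for every stored pair")
    if (anyDuplicated(paste(a$pdb_id, a$pmc_id)))
      msgs <- c(msgs, "(pdb_id, pmc_id) pairs must be unique")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "AssociationTable", function(object) {
  a <- object@assoc
  cat("AssociationTable: ", length(unique(a$pdb_id)), " PDB ids across ",
      length(unique(a$pmc_id)), " articles (",
      nrow(a), " pairs)\n", sep = "")
})

#' Aggregate corpus mentions into an association table
#'
#' @param mentions corpus-wide mention data.frame (from
#'   \code{\link{mineCorpus}}); only \code{pdb_id} and \code{pmc_id} are
#'   used.
#' @return an \linkS4class{AssociationTable}.
#' @export
buildAssociations <- function(mentions) {
  if (nrow(mentions) == 0L) {
    return(new("AssociationTable", assoc = data.frame(
      pdb_id = character(), pmc_id = character(),
      mention_count = integer(), stringsAsFactors = FALSE)))
  }
  tab <- as.data.frame(table(pdb_id = mentions$pdb_id,
                             pmc_id = mentions$pmc_id),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  tab <- tab[order(tab$pdb_id, tab$pmc_id), , drop = FALSE]
  names(tab)[3] <- "mention_count"
  tab$mention_count <- as.integer(tab$mention_count)
  rownames(tab) <- NULL
  new("AssociationTable", assoc = tab)
}

#' @rdname buildAssociations
#' @param x an AssociationTable.
#' @export
setGeneric("associations", function(x) standardGeneric("associations"))

#' @rdname buildAssociations
setMethod("associations", "AssociationTable", function(x) x@assoc)

#' @rdname buildAssociations
#' @export
setGeneric("articlesById", function(x) standardGeneric("articlesById"))

#' @rdname buildAssociations
setMethod("articlesById", "AssociationTable", function(x)
  split(x@assoc$pmc_id, x@assoc$pdb_id))

#' @rdname buildAssociations
#' @export
setGeneric("idsByArticle", function(x) standardGeneric("idsByArticle"))

#' @rdname buildAssociations
setMethod("idsByArticle", "AssociationTable", function(x)
  split(x@assoc$pdb_id, x@assoc$pmc_id))

#' List structures co-occurring with a target PDB id
#'
#' Co-occurring ids are the other PDB ids found in the same articles as the
#' target.  Pairs are sorted by number of shared articles (descending), then
#' lexicographically by partner id.  When chain sequences are supplied the
#' pair is annotated with the best-chain percent identity (see
#' \code{\link{bestChainSimilarity}}).
#'
#' @param table an \linkS4class{AssociationTable}.
#' @param pdbId target identifier (any case).
#' @param chainSets optional named list (by PDB id) of named chain sequence
#'   vectors, e.g. from \code{\link{readChainFasta}}.
#' @return data.frame with columns \code{id_a}, \code{id_b} (the pair in
#'   lexicographic order), \code{partner} (the non-target id),
#'   \code{n_shared}, \code{shared_articles} (";"-joined pmc ids, sorted),
#'   and, when sequences for both entries are available,
#'   \code{identity_percent}, \code{chain_a}, \code{chain_b} (NA otherwise).
#' @export
cooccurringIds <- function(table, pdbId, chainSets = NULL) {
  stopifnot(is(table, "AssociationTable"))
  pdbId <- toupper(pdbId)
  byArt <- idsByArticle(table)
  byId <- articlesById(table)
  mine <- byId[[pdbId]]
  empty <- data.frame(id_a = character(), id_b = character(),
                      partner = character(), n_shared = integer(),
                      shared_articles = character(),
                      identity_percent = numeric(), chain_a = character(),
                      chain_b = character(), stringsAsFactors = FALSE)
  if (is.null(mine)) return(empty)
  partners <- setdiff(unique(unlist(byArt[mine], use.names = FALSE)), pdbId)
  if (!length(partners)) return(empty)
  rows <- lapply(sort(partners), function(p) {
    shared <- sort(intersect(mine, byId[[p]]))
    data.frame(id_a = min(pdbId, p), id_b = max(pdbId, p), partner = p,
               n_shared = length(shared),
               shared_articles = paste(shared, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_shared, out$partner), , drop = FALSE]
  rownames(out) <- NULL
  out$identity_percent <- NA_real_
  out$chain_a <- NA_character_
  out$chain_b <- NA_character_
  if (!is.null(chainSets)) {
    for (i in seq_len(nrow(out))) {
      ca <- chainSets[[out$id_a[i]]]
      cb <- chainSets[[out$id_b[i]]]
      if (!is.null(ca) && !is.null(cb)) {
        best <- bestChainSimilarity(ca, cb)
        out$identity_percent[i] <- best$identity
        out$chain_a[i] <- best$chain_a
        out$chain_b[i] <- best$chain_b
      }
    }
  }
  out
}

#' Rank structures by distinct-article count
#'
#' "Article count" is the number of distinct articles mentioning the
#' structure, not the total number of mentions.  Ties are broken
#' lexicographically by id.
#'
#' @param table an \linkS4class{AssociationTable}.
#' @param k number of top structures to return (>= 1).
#' @return data.frame with columns \code{pdb_id}, \code{article_count},
#'   at most k rows, most-cited first.
#' @export
rankByArticleCount <- function(table, k) {
  stopifnot(is(table, "AssociationTable"), k >= 1L)
  a <- associations(table)
  if (nrow(a) == 0L)
    return(data.frame(pdb_id = character(), article_count = integer(),
                      stringsAsFactors = FALSE))
  counts <- vapply(split(a$pmc_id, a$pdb_id),
                   function(v) length(unique(v)), integer(1))
  ids <- names(counts)
  o <- order(-counts, ids)
  res <- data.frame(pdb_id = ids[o], article_count = unname(counts[o]),
                    stringsAsFactors = FALSE)
  head(res, k)
}

.aaAlphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

.checkSeq <- function(s, arg) {
  if (!is.character(s) || length(s) != 1L || !nzchar(s))
    stop("argument error: ", arg, " must be a single non-empty sequence")
  ch <- strsplit(toupper(s), "")[[1]]
  bad <- setdiff(ch, .aaAlphabet)
  if (length(bad))
    stop("argument error: non-amino-acid character(s) in ", arg, ": ",
         paste(unique(bad), collapse = ", "))
  ch
}

#' Global-alignment percent identity between two protein sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1 and linear
#' gap penalty -1.  Identity is 100 x matching columns / alignment columns,
#' where the denominator counts gap columns too.  The traceback resolves
#' score ties deterministically: diagonal first, then up (gap in \code{b}),
#' then left; the reported identity is that of this one optimal alignment.
#'
#' @param a,b amino-acid sequences (one-letter codes, 20 standard + X;
#'   case-insensitive).
#' @param match,mismatch,gap scoring parameters.
#' @return percent identity in [0, 100], with attributes \code{score},
#'   \code{matches} and \code{columns} describing the reported alignment.
#' @examples
#' sequenceIdentity("ACDE", "ACDE")  # 100
#' sequenceIdentity("AAAA", "CCCC")  # 0
#' @export
sequenceIdentity <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  av <- .checkSeq(a, "a")
  bv <- .checkSeq(b, "b")
  n <- length(av); m <- length(bv)

  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- gap * (0:n)
  S[1L, ] <- gap * (0:m)
  sub <- outer(av, bv, function(x, y) ifelse(x == y, match, mismatch))
  for (i in seq_len(n)) {
    # vectorised over j is impossible (left-dependency), so roll by row
    row <- S[i + 1L, ]
    prev <- S[i, ]
    row[1L] <- gap * i
    for (j in seq_len(m)) {
      row[j + 1L] <- max(prev[j] + sub[i, j], prev[j + 1L] + gap,
                         row[j] + gap)
    }
    S[i + 1L, ] <- row
  }

  # traceback, tie order: diagonal, then up (consume a), then left
  i <- n; j <- m; matches <- 0L; columns <- 0L
  while (i > 0L || j > 0L) {
    columns <- columns + 1L
    if (i > 0L && j > 0L && S[i + 1L, j + 1L] == S[i, j] + sub[i, j]) {
      if (av[i] == bv[j]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  structure(100 * matches / columns,
            score = S[n + 1L, m + 1L], matches = matches, columns = columns)
}

#' Best-chain similarity between two multi-chain entries
#'
#' When a structure contains multiple chains, the chain pair with the
#' highest global-alignment percent identity is reported.  Ties are broken
#' by the lexicographic order of (chain of a, chain of b).
#'
#' @param a,b named character vectors of chain sequences
#'   (\code{chain_id = sequence}); must be non-empty.
#' @param ... passed to \code{\link{sequenceIdentity}}.
#' @return list with \code{identity} (percent), \code{chain_a},
#'   \code{chain_b}.
#' @export
bestChainSimilarity <- function(a, b, ...) {
  if (!length(a) || !length(b))
    stop("argument error: both chain sets must be non-empty")
  if (is.null(names(a)) || is.null(names(b)))
    stop("argument error: chain sets must be named by chain id")
  best <- NULL
  for (ca in sort(names(a))) {
    for (cb in sort(names(b))) {
      idt <- as.numeric(sequenceIdentity(a[[ca]], b[[cb]], ...))
      if (is.null(best) || idt > best$identity)
        best <- list(identity = idt, chain_a = ca, chain_b = cb)
    }
  }
  best
}

#' Read per-entry chain sequences from FASTA
#'
#' Headers must follow the convention \code{PDBID_CHAIN} (e.g.
#' \code{1ABC_A}).  Uses Biostrings when available, else a minimal reader.
#'
#' @param path FASTA file of amino-acid chain sequences.
#' @return named list: \code{pdb_id} -> named character vector of chains.
#' @export
readChainFasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readAAStringSet(path)
    headers <- names(ss)
    seqs <- as.character(ss)
  } else {
    lines <- readLines(path, warn = FALSE)
    hi <- grep("^>", lines)
    headers <- sub("^>\\s*", "", lines[hi])
    ends <- c(hi[-1] - 1L, length(lines))
    seqs <- vapply(seq_along(hi), function(k)
      paste(lines[seq(hi[k] + 1L, ends[k])], collapse = ""), character(1))
  }
  headers <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  parts <- strsplit(headers, "_", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad))
    stop("FASTA headers must follow PDBID_CHAIN; offending: ",
         paste(head(headers[bad], 3), collapse = ", "))
  entry <- toupper(vapply(parts, `[`, character(1), 1L))
  chain <- vapply(parts, `[`, character(1), 2L)
  out <- list()
  for (k in seq_along(entry)) {
    out[[entry[k]]] <- c(out[[entry[k]]],
                         stats::setNames(toupper(seqs[k]), chain[k]))
  }
  out
}
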