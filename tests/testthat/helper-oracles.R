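# Independent brute-force oracles.  These deliberately avoid the package's
# own code paths: the candidate oracle tests every length-4 substring, the
# tagging oracle enumerates every token-aligned substring, and the alignment
# oracle enumerates every global alignment.

# Every length-4 substring that satisfies the candidate predicate and is not
# adjacent to an alphanumeric character.  Offsets 0-based half-open.
bruteCandidates <- function(text) {
  out <- list()
  n <- nchar(text)
  isAlnum <- function(ch) grepl("^[A-Za-z0-9]$", ch)
  for (s in seq_len(max(n - 3L, 0L))) {
    tok <- substr(text, s, s + 3L)
    if (!grepl("^[1-9][A-Za-z0-9]{3}$", tok)) next
    if (!grepl("[A-Za-z]", tok)) next
    if (s > 1L && isAlnum(substr(text, s - 1L, s - 1L))) next
    if (s + 4L <= n && isAlnum(substr(text, s + 4L, s + 4L))) next
    out[[length(out) + 1L]] <- data.frame(
      token = tok, start = s - 1L, end = s + 3L, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(token = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Greedy longest-leftmost dictionary tagging by exhaustive substring lookup.
bruteTagTerms <- function(text, dictionary) {
  e <- dictionaryEntries(dictionary)
  m <- gregexpr("[A-Za-z0-9]+", text)[[1]]
  empty <- data.frame(term_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (nrow(e) == 0L || m[1] == -1L) return(empty)
  tokStart <- as.integer(m)
  tokEnd <- tokStart + attr(m, "match.length") - 1L
  toks <- tolower(substring(text, tokStart, tokEnd))
  n <- length(toks)
  maxLen <- max(e$n_tokens)
  out <- list()
  i <- 1L
  while (i <= n) {
    best <- NULL
    for (len in seq_len(min(maxLen, n - i + 1L))) {
      key <- paste(toks[i:(i + len - 1L)], collapse = " ")
      hit <- e[e$surface == key, , drop = FALSE]
      if (nrow(hit))
        best <- list(len = len, id = min(hit$term_id))
    }
    if (!is.null(best)) {
      out[[length(out) + 1L]] <- data.frame(
        term_id = best$id, start = tokStart[i] - 1L,
        end = tokEnd[i + best$len - 1L], stringsAsFactors = FALSE)
      i <- i + best$len
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# Exhaustive global-alignment oracle.  Enumerates every alignment (move
# sequences over diagonal D, up U = consume a, left L = consume b), scores
# each, and among the optimal ones selects the alignment a backward
# traceback with tie order D, U, L would report: the one whose reversed
# move sequence is lexicographically smallest under D < U < L.
enumAlignIdentity <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  paths <- list()
  rec <- function(i, j, moves) {
    if (i == n && j == m) {
      paths[[length(paths) + 1L]] <<- moves
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1L, j + 1L, c(moves, "D"))
    if (i < n) rec(i + 1L, j, c(moves, "U"))
    if (j < m) rec(i, j + 1L, c(moves, "L"))
  }
  rec(0L, 0L, character())
  scorePath <- function(mv) {
    i <- 0L; j <- 0L; sc <- 0; mt <- 0L
    for (x in mv) {
      if (x == "D") {
        i <- i + 1L; j <- j + 1L
        if (av[i] == bv[j]) { sc <- sc + match; mt <- mt + 1L }
        else sc <- sc + mismatch
      } else if (x == "U") { i <- i + 1L; sc <- sc + gap }
      else { j <- j + 1L; sc <- sc + gap }
    }
    list(score = sc, matches = mt, columns = length(mv))
  }
  scored <- lapply(paths, scorePath)
  scores <- vapply(scored, function(x) x$score, numeric(1))
  best <- which(scores == max(scores))
  rank <- c(D = 1L, U = 2L, L = 3L)
  key <- vapply(best, function(k)
    paste(sprintf("%d", rank[rev(paths[[k]])]), collapse = ""), character(1))
  pick <- best[order(key)][1]
  list(score = max(scores),
       identity = 100 * scored[[pick]]$matches / scored[[pick]]$columns,
       matches = scored[[pick]]$matches,
       columns = scored[[pick]]$columns)
}

# Random plain text over a vocabulary, with optional planted phrases.
randomText <- function(nTokens, vocab, planted = character()) {
  words <- sample(vocab, nTokens, replace = TRUE)
  for (p in planted) {
    pos <- sample(length(words), 1)
    words <- append(words, p, after = pos)
  }
  paste(words, collapse = " ")
}

# Shared small fixture: lexicon + one corpus + parsed articles + mined
# mentions, built once per test run.
fixtureCorpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lex <- generateLexicon(60, 8, seed = 401)
      obo <- generateOBO(80, synonymRate = 0.3, seed = 402)
      act <- obo$manifest[!obo$manifest$obsolete, ]
      termList <- data.frame(
        term_id = c(act$term_id, act$term_id[!is.na(act$synonym)]),
        surface = c(act$name, act$synonym[!is.na(act$synonym)]),
        stringsAsFactors = FALSE)
      sp <- plantSpec(nArticles = 25, seed = 403)
      cor <- generateCorpus(sp, lex, termList = termList)
      arts <- lapply(cor$xml, parseJATS)
      cache <<- list(lexicon = lex, obo = obo, termList = termList,
                     spec = sp, corpus = cor, articles = arts,
                     mentions = mineCorpus(arts, lex))
    }
    cache
  }
})

sortMentions <- function(df) {
  df <- df[order(df$pmc_id, df$unit_id, df$start),
           c("pmc_id", "pdb_id", "unit_id", "start", "end"), drop = FALSE]
  rownames(df) <- NULL
  df
}
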