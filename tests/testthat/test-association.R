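mentionRows <- function(pdb, pmc) {
  data.frame(pdb_id = pdb, pmc_id = pmc, unit_id = "p-1",
             unit_kind = "body_para", start = 0L, end = 4L,
             context = "", cue_found = FALSE, stringsAsFactors = FALSE)
}

test_that("associations aggregate mention counts per (id, article) pair", {
  men <- mentionRows(rep("1HIV", 4), c("A", "A", "A", "B"))
  tab <- buildAssociations(men)
  a <- associations(tab)
  expect_equal(a$pmc_id, c("A", "B"))
  expect_equal(a$mention_count, c(3L, 1L))

  empty <- buildAssociations(men[0, ])
  expect_equal(nrow(associations(empty)), 0L)
})

test_that("by-id and by-article views are transposes; pairs are conserved", {
  fx <- fixtureCorpus()
  tab <- buildAssociations(fx$mentions)
  byId <- articlesById(tab)
  byArt <- idsByArticle(tab)
  for (id in names(byId))
    for (pmc in byId[[id]])
      expect_true(id %in% byArt[[pmc]])
  expect_equal(sum(lengths(byId)), sum(lengths(byArt)))
  # and the table equals an independent tally of the truth manifest
  man <- fx$corpus$manifest$mentions
  want <- aggregate(list(mention_count = man$pdb_id),
                    by = list(pdb_id = man$pdb_id, pmc_id = man$pmc_id),
                    FUN = length)
  want <- want[order(want$pdb_id, want$pmc_id), c("pdb_id", "pmc_id",
                                                  "mention_count")]
  got <- associations(tab)
  rownames(want) <- rownames(got) <- NULL
  want$mention_count <- as.integer(want$mention_count)
  expect_identical(got, want)
})

test_that("co-occurrence enumerates shared-article partners in order", {
  men <- mentionRows(c("1AAA", "2BBB", "1AAA"), c("A", "A", "B"))
  tab <- buildAssociations(men)
  co <- cooccurringIds(tab, "1AAA")
  expect_equal(co$partner, "2BBB")
  expect_equal(co$n_shared, 1L)
  expect_equal(co$shared_articles, "A")
  # an article with a single id contributes no pairs
  expect_equal(nrow(cooccurringIds(tab, "2BBB")), 1L)  # only via article A
  expect_equal(nrow(cooccurringIds(tab, "9ZZZ")), 0L)
})

test_that("co-occurrence matches a brute-force double loop and is symmetric", {
  set.seed(701)
  ids <- replicate(30, pdbmine:::.randomPdbId())
  arts <- paste0("PMC", 1:200)
  men <- do.call(rbind, lapply(arts, function(a)
    mentionRows(sample(ids, sample(1:5, 1)), a)))
  tab <- buildAssociations(men)

  idsOf <- split(men$pdb_id, men$pmc_id)
  bruteShared <- function(x, y) {
    sort(names(Filter(function(v) x %in% v && y %in% v, idsOf)))
  }
  for (target in sample(ids, 5)) {
    co <- cooccurringIds(tab, target)
    # brute force over every other id
    for (other in setdiff(ids, target)) {
      shared <- bruteShared(target, other)
      row <- co[co$partner == other, ]
      if (length(shared)) {
        expect_equal(row$n_shared, length(shared))
        expect_equal(row$shared_articles, paste(shared, collapse = ";"))
        # symmetry
        back <- cooccurringIds(tab, other)
        expect_equal(back$shared_articles[back$partner == target],
                     row$shared_articles)
      } else {
        expect_equal(nrow(row), 0L)
      }
    }
    expect_true(all(diff(co$n_shared) <= 0))
  }
})

test_that("ranking counts distinct articles with lexicographic ties", {
  men <- mentionRows(c("2BBB", "2BBB", "2BBB", "1AAA", "1AAA", "3CCC"),
                     c("A", "A", "B", "C", "D", "E"))
  got <- rankByArticleCount(buildAssociations(men), 3)
  # 2BBB: 2 articles (3 mentions); 1AAA: 2; 3CCC: 1
  expect_equal(got$pdb_id, c("1AAA", "2BBB", "3CCC"))
  expect_equal(got$article_count, c(2L, 2L, 1L))
  expect_equal(nrow(rankByArticleCount(buildAssociations(men[0, ]), 5)), 0L)
})

test_that("percent identity behaves at the fixed points", {
  expect_equal(as.numeric(sequenceIdentity("ACDE", "ACDE")), 100)
  expect_equal(as.numeric(sequenceIdentity("AAAA", "CCCC")), 0)
  # frozen from the exhaustive-enumeration oracle: 3 matches / 4 columns
  expect_equal(as.numeric(sequenceIdentity("ACDE", "ACE")), 75)
  expect_error(sequenceIdentity("", "ACDE"), "argument error")
  expect_error(sequenceIdentity("ACDE", "ACBZ"), "argument error")
})

test_that("percent identity is symmetric and 100 iff equal", {
  set.seed(702)
  alpha <- c("A", "C", "D", "E", "G", "K")
  for (k in 1:30) {
    a <- paste(sample(alpha, sample(2:10, 1), TRUE), collapse = "")
    b <- paste(sample(alpha, sample(2:10, 1), TRUE), collapse = "")
    expect_equal(as.numeric(sequenceIdentity(a, b)),
                 as.numeric(sequenceIdentity(b, a)))
    if (identical(a, b))
      expect_equal(as.numeric(sequenceIdentity(a, b)), 100)
  }
  expect_lt(as.numeric(sequenceIdentity("ACDE", "ACD")), 100)
})

test_that("best-chain similarity maximises over the chain cross-product", {
  a <- c(A = "ACDEFGHIKL")
  b <- c(A = "MNPQRSTVWY", B = "ACDEFGHIKL")
  best <- bestChainSimilarity(a, b)
  expect_equal(best$identity, 100)
  expect_equal(best$chain_b, "B")

  # single-chain pairs reduce to sequenceIdentity
  expect_equal(bestChainSimilarity(c(A = "ACDE"), c(A = "ACE"))$identity,
               as.numeric(sequenceIdentity("ACDE", "ACE")))

  set.seed(703)
  alpha <- c("A", "C", "D", "E", "G")
  for (k in 1:5) {
    ca <- stats::setNames(replicate(3, paste(
      sample(alpha, sample(5:20, 1), TRUE), collapse = "")), c("A", "B", "C"))
    cb <- stats::setNames(replicate(3, paste(
      sample(alpha, sample(5:20, 1), TRUE), collapse = "")), c("A", "B", "C"))
    best <- bestChainSimilarity(ca, cb)
    all9 <- outer(names(ca), names(cb), Vectorize(function(x, y)
      as.numeric(sequenceIdentity(ca[[x]], cb[[y]]))))
    expect_equal(best$identity, max(all9))
  }
  expect_error(bestChainSimilarity(c(A = "ACDE"), character()),
               "argument error")
})

test_that("co-occurring pairs pick up best-chain identity from FASTA", {
  fa <- generateChainFasta(nEntries = 3, chainsPerEntry = 2,
                           mutationRate = 0.05, seed = 31, length = 60)
  path <- withr::local_tempfile(lines = fa$fasta)
  chains <- readChainFasta(path)
  expect_identical(chains, fa$chains)

  ids <- names(chains)
  men <- mentionRows(c(ids[1], ids[2], ids[1], ids[3]),
                     c("A", "A", "B", "B"))
  tab <- buildAssociations(men)
  co <- cooccurringIds(tab, ids[1], chainSets = chains)
  expect_equal(nrow(co), 2L)
  want <- bestChainSimilarity(chains[[co$id_a[1]]], chains[[co$id_b[1]]])
  expect_equal(co$identity_percent[1], want$identity)
  expect_equal(co$chain_a[1], want$chain_a)
  # without sequences the identity column is absent (NA)
  expect_true(all(is.na(cooccurringIds(tab, ids[1])$identity_percent)))
})

test_that("mutant chains sit at the identity the mutation count dictates", {
  L <- 200
  fa0 <- generateChainFasta(nEntries = 2, chainsPerEntry = 1,
                            mutationRate = 0, seed = 32, length = L)
  seqs <- unlist(fa0$chains)
  expect_equal(as.numeric(sequenceIdentity(seqs[1], seqs[2])), 100)

  fa <- generateChainFasta(nEntries = 2, chainsPerEntry = 1,
                           mutationRate = 0.05, seed = 33, length = L)
  m <- fa$manifest$n_mutations[2]
  mutant <- unlist(fa$chains)[2]
  # position-wise (gapless) identity is exactly fixed by the mutation count
  hamming <- 100 * mean(strsplit(fa$ancestor, "")[[1]] ==
                          strsplit(mutant, "")[[1]])
  expect_equal(hamming, 100 * (L - m) / L)
  # the aligner may do marginally better via gaps, never worse, and stays
  # within sampling tolerance of 100 * (1 - mutationRate)
  got <- as.numeric(sequenceIdentity(fa$ancestor, mutant))
  expect_gte(got, hamming)
  expect_equal(got, 100 * (1 - 0.05), tolerance = 0.05)
})
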