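test_that("impossible corpus specifications are rejected up front", {
  expect_error(plantSpec(idsPerArticle = c(3, 2)), "configuration error")
  expect_error(plantSpec(decoyYears = c(-1, 1)), "configuration error")
  lex <- generateLexicon(3, 0, seed = 1)
  expect_error(generateCorpus(plantSpec(idsPerArticle = c(4, 8)), lex),
               "configuration error")
  expect_error(
    generateCorpus(plantSpec(decoyCuelessBlacklist = c(1, 1)),
                   generateLexicon(20, 0, seed = 2)),
    "configuration error")
})

test_that("an empty specification yields an empty corpus and manifest", {
  lex <- generateLexicon(10, 1, seed = 3)
  cor <- generateCorpus(plantSpec(nArticles = 0), lex)
  expect_equal(length(cor$xml), 0L)
  expect_equal(nrow(cor$manifest$mentions), 0L)
  expect_equal(nrow(cor$manifest$units), 0L)
})

test_that("generation is a pure function of the seed", {
  lex <- generateLexicon(30, 4, seed = 4)
  sp <- plantSpec(nArticles = 6, seed = 99)
  a <- generateCorpus(sp, lex)
  b <- generateCorpus(sp, lex)
  expect_identical(a$xml, b$xml)          # byte-identical
  expect_identical(a$manifest, b$manifest)
  other <- generateCorpus(plantSpec(nArticles = 6, seed = 100), lex)
  expect_false(identical(a$xml, other$xml))
  # and the generators do not disturb the caller's RNG stream
  set.seed(5); x <- runif(1)
  set.seed(5); invisible(generateCorpus(sp, lex)); y <- runif(1)
  expect_identical(x, y)
})

test_that("manifest offsets re-locate in the parsed articles", {
  lex <- generateLexicon(40, 6, seed = 6)
  cor <- generateCorpus(plantSpec(nArticles = 10, seed = 7), lex)
  for (pmc in names(cor$xml)) {
    art <- parseJATS(cor$xml[[pmc]])
    u <- textUnits(art)
    rows <- cor$manifest$mentions[cor$manifest$mentions$pmc_id == pmc, ]
    dec <- cor$manifest$decoys[cor$manifest$decoys$pmc_id == pmc, ]
    both <- rbind(rows[, c("unit_id", "start", "end")],
                  dec[, c("unit_id", "start", "end")])
    both$token <- c(rows$pdb_id, dec$token)
    for (i in seq_len(nrow(both))) {
      txt <- u$text[match(both$unit_id[i], u$unit_id)]
      expect_equal(substr(txt, both$start[i] + 1L, both$end[i]),
                   both$token[i])
    }
  }
})

test_that("blacklisted plants come in both cue flavours", {
  lex <- generateLexicon(30, 10, seed = 8)
  cor <- generateCorpus(plantSpec(nArticles = 40, seed = 9,
                                  decoyCuelessBlacklist = c(1, 1)), lex)
  man <- cor$manifest
  expect_gt(sum(man$mentions$blacklisted), 0)          # with cue, survive
  expect_gt(sum(man$decoys$type == "cueless_blacklist"), 0)  # filtered
  expect_true(all(man$mentions$has_cue[man$mentions$blacklisted]))
})

test_that("the written corpus directory round-trips", {
  dir <- withr::local_tempdir()
  lex <- generateLexicon(20, 2, seed = 10)
  cor <- generateCorpus(plantSpec(nArticles = 4, seed = 11), lex, dir = dir)
  files <- list.files(dir, pattern = "\\.xml$")
  expect_equal(length(files), 4L)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  onDisk <- readCorpus(dir)
  inMem <- lapply(cor$xml, parseJATS)
  expect_identical(lapply(onDisk, textUnits), lapply(inMem, textUnits))
})

test_that("ontology generation matches its manifest", {
  obo <- generateOBO(25, synonymRate = 0.5, seed = 12, nObsolete = 2)
  man <- obo$manifest
  expect_equal(sum(!man$obsolete), 25L)
  expect_equal(sum(man$obsolete), 2L)
  expect_identical(generateOBO(25, synonymRate = 0.5, seed = 12,
                               nObsolete = 2)$obo, obo$obo)
  expect_equal(nrow(generateOBO(0, seed = 13, nObsolete = 0)$manifest), 0L)
  d <- loadOBO(generateOBO(0, seed = 13, nObsolete = 0)$obo)
  expect_equal(nrow(dictionaryEntries(d)), 0L)
})

test_that("chain FASTA generation is seed-deterministic with exact counts", {
  fa <- generateChainFasta(nEntries = 4, chainsPerEntry = 3,
                           mutationRate = 0.1, seed = 14, length = 80)
  expect_equal(nrow(fa$manifest), 12L)
  expect_equal(fa$manifest$n_mutations[1], 0L)  # first chain is the ancestor
  expect_identical(
    generateChainFasta(nEntries = 4, chainsPerEntry = 3,
                       mutationRate = 0.1, seed = 14, length = 80)$fasta,
    fa$fasta)
  # mutation counts re-derive from the sequences themselves
  anc <- strsplit(fa$ancestor, "")[[1]]
  k <- 0L
  for (id in names(fa$chains)) {
    for (ch in names(fa$chains[[id]])) {
      k <- k + 1L
      diffs <- sum(strsplit(fa$chains[[id]][[ch]], "")[[1]] != anc)
      expect_equal(diffs, fa$manifest$n_mutations[k])
    }
  }
})
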