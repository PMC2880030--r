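test_that("candidate detection matches the documented pattern", {
  got <- findCandidates("the PDB ID 3BY7 was cited")
  expect_equal(got$token, "3BY7")
  expect_equal(got$start, 11L)
  expect_equal(got$end, 15L)

  expect_equal(nrow(findCandidates("published in 2009 and 2010")), 0L)
  expect_equal(nrow(findCandidates("")), 0L)
  expect_equal(nrow(findCandidates("0ABC starts with zero")), 0L)

  # hyphen/underscore/punctuation are boundaries; alphanumerics are not
  expect_equal(findCandidates("PDB:1HIV and (1kx3)")$token,
               c("1HIV", "1kx3"))
  expect_equal(findCandidates("1HIV-tag plus his_2abc done")$token,
               c("1HIV", "2abc"))
  expect_equal(nrow(findCandidates("x1HIV 1HIVx 11HIV")), 0L)
})

test_that("candidate detection agrees with a brute-force substring scan", {
  set.seed(501)
  vocab <- c("folded", "with", "the", "1ABC", "9xy1", "2009", "rmsd",
             "(3ER5)", "pdb:4Q9Z", "a1BCD", "x", "30L1,")
  for (k in 1:40) {
    text <- paste(sample(vocab, 30, replace = TRUE), collapse = " ")
    got <- findCandidates(text)
    want <- bruteCandidates(text)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("validation keeps exactly the lexicon ids, case-insensitively", {
  lex <- IdLexicon(c("3BY7", "1HIV"))
  cand <- data.frame(token = c("3BY7", "9ZZZ", "1hiv"),
                     start = c(0L, 10L, 20L), end = c(4L, 14L, 24L),
                     stringsAsFactors = FALSE)
  men <- validateCandidates(cand, lex, "77", "p-1", "body_para")
  expect_equal(men$pdb_id, c("3BY7", "1HIV"))  # canonical uppercase
  expect_equal(men$start, c(0L, 20L))

  expect_equal(nrow(validateCandidates(cand[0, ], lex, "77", "p-1",
                                       "body_para")), 0L)
  expect_error(
    validateCandidates(cand, IdLexicon(character()), "77", "p-1",
                       "body_para"),
    "configuration error")
})

test_that("blacklisted ids need a cue term in the same unit", {
  lex <- IdLexicon(c("3DNA", "1HIV"), blacklist = "3DNA")

  mine1 <- function(text) {
    men <- validateCandidates(findCandidates(text), lex, "77", "p-1",
                              "body_para")
    applyBlacklistFilter(men, text, lex)
  }
  expect_equal(nrow(mine1("experiments used the 3DNA software package")), 0L)

  kept <- mine1("PDB entry 3DNA shows the duplex")
  expect_equal(kept$pdb_id, "3DNA")
  expect_true(kept$cue_found)

  # non-blacklisted ids pass without a cue, and cue_found is still recorded
  plain <- mine1("binding of 1HIV was measured")
  expect_equal(plain$pdb_id, "1HIV")
  expect_false(plain$cue_found)
})

test_that("enlarging the blacklist never increases returned mentions", {
  fx <- fixtureCorpus()
  lex <- fx$lexicon
  bigger <- IdLexicon(validIds(lex),
                      blacklist = validIds(lex)[1:30],
                      cueTerms = cueTerms(lex))
  n0 <- nrow(mineCorpus(fx$articles, lex))
  n1 <- nrow(mineCorpus(fx$articles, bigger))
  expect_lte(n1, n0)
})

test_that("context is the containing paragraph, or the legend for captions", {
  xml <- paste0(
    '<article><front><article-meta>',
    '<article-id pub-id-type="pmc">9</article-id>',
    '<title-group><article-title>t</article-title></title-group>',
    '</article-meta></front>',
    '<body><p>The model 1KX3 fits the density well</p><p>1HIV</p>',
    '<fig id="f1"><caption><p>Overall fold of 1KX3</p></caption></fig>',
    '</body></article>')
  art <- parseJATS(xml)
  lex <- IdLexicon(c("1KX3", "1HIV"))
  men <- mineArticle(art, lex)

  expect_equal(men$context[men$unit_id == "p-1"],
               "The model 1KX3 fits the density well")
  expect_equal(men$context[men$unit_id == "p-2"], "1HIV")  # unit = context
  expect_equal(men$context[men$unit_id == "cap-f1"],
               "Overall fold of 1KX3")
  expect_equal(
    extractContext(art, list(unit_id = "cap-f1")),
    "Overall fold of 1KX3")
  expect_error(extractContext(art, list(unit_id = "p-99")), "unknown unit_id")
})

test_that("mined spans re-read from the unit text and ids are valid", {
  fx <- fixtureCorpus()
  men <- fx$mentions
  expect_true(all(men$pdb_id %in% validIds(fx$lexicon)))
  units <- fx$corpus$manifest$units
  key <- paste(units$pmc_id, units$unit_id)
  for (i in seq_len(nrow(men))) {
    txt <- units$text[match(paste(men$pmc_id[i], men$unit_id[i]), key)]
    expect_equal(toupper(substr(txt, men$start[i] + 1L, men$end[i])),
                 men$pdb_id[i])
  }
})

test_that("mining is deterministic and case-invariant", {
  fx <- fixtureCorpus()
  art <- fx$articles[[3]]
  expect_identical(mineArticle(art, fx$lexicon),
                   mineArticle(art, fx$lexicon))

  lowered <- art
  u <- textUnits(art)
  u$text <- tolower(u$text)
  lowered@units <- u
  lowered@figures$caption <- tolower(lowered@figures$caption)
  expect_identical(sort(mineArticle(lowered, fx$lexicon)$pdb_id),
                   sort(mineArticle(art, fx$lexicon)$pdb_id))
})

test_that("lexicon files read with comments and case folding", {
  path <- withr::local_tempfile(lines = c("# synthetic ids", "1abc",
                                          "2DEF  # trailing note", ""))
  bl <- withr::local_tempfile(lines = "2def")
  lex <- readLexicon(path, blacklistPath = bl)
  expect_setequal(validIds(lex), c("1ABC", "2DEF"))
  expect_equal(idBlacklist(lex), "2DEF")
  expect_true("PDB" %in% cueTerms(lex))
})
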