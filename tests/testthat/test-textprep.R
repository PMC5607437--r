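test_that("normalization lowercases, strips punctuation and transliterates accents", {
  expect_equal(normalize_query("Where are cooking classes in Portland?"),
               "where are cooking classes in portland")
  expect_equal(normalize_query("ű"), "u")      # u with double acute
  expect_equal(normalize_query("café"), "cafe")
  expect_equal(normalize_query(""), "")
  expect_equal(normalize_query("???!!"), "")
  # punctuation is removed in place, not treated as a separator
  expect_equal(normalize_query("high-tech it's"), "hightech its")
  # unreadable characters (not transliterable) vanish
  expect_equal(normalize_query("abc中文def"), "abcdef")
  # whitespace runs collapse
  expect_equal(normalize_query("  a\t b\n c "), "a b c")
})

test_that("tokenization splits on whitespace runs and drops empties", {
  expect_equal(tokenize_query("where are cooking classes in portland"),
               c("where", "are", "cooking", "classes", "in", "portland"))
  expect_equal(tokenize_query("a  b"), c("a", "b"))
  expect_equal(tokenize_query("   "), character(0))
})

test_that("spell correction follows the tiered candidate scheme", {
  cp <- word_corpus(c("class", "lass"), c(10, 1))
  expect_equal(spell_correct("classs", cp), "class")     # tier-1 deletion
  cp2 <- word_corpus("word", 50)
  expect_equal(spell_correct("wrod", cp2), "word")       # tier-2 swap
  cp3 <- example_corpus()
  expect_equal(spell_correct("portland", cp3), "portland")  # in-corpus
  expect_equal(spell_correct("qzxv", cp3), "qzxv")          # no tier hits
  expect_equal(spell_correct("12345", cp3), "12345")        # numeric bypass
  # earlier tier wins even when later tiers also contain corpus words
  cp4 <- word_corpus(c("cat", "cart"), c(1, 1000))
  expect_equal(spell_correct("catt", cp4), "cat")  # deletion beats insertion
  # ties broken by frequency, then lexicographically
  cp5 <- word_corpus(c("bat", "cat"), c(5, 9))
  expect_equal(spell_correct("at", cp5), "cat")
  cp6 <- word_corpus(c("bat", "cat"), c(7, 7))
  expect_equal(spell_correct("at", cp6), "bat")
})

test_that("spell correction agrees with the exhaustive-candidate oracle", {
  set.seed(11)
  vocab <- unique(replicate(400, rand_word(sample(3:9, 1))))
  cp <- word_corpus(vocab, sample(1:1000, length(vocab), replace = TRUE))
  words <- sample(vocab, 150, replace = TRUE)
  corrupted <- vapply(words, corrupt_once, "")
  got <- spell_correct(corrupted, cp)
  want <- vapply(corrupted, oracle_spell, "", corpus = cp)
  expect_equal(unname(got), unname(want))
  # fixed point: in-corpus tokens never change, corrections land in-corpus
  expect_equal(spell_correct(vocab, cp), vocab)
  changed <- got != corrupted
  expect_true(all(got[changed] %in% cp$word))
})

test_that("lemmatization validates roots against the corpus", {
  cp <- example_corpus()
  expect_equal(lemmatize_token("classes", cp), "class")
  expect_equal(lemmatize_token("cooking", cp), "cook")
  expect_equal(lemmatize_token("wolves", cp), "wolf")
  expect_equal(lemmatize_token("dies", cp), "die")   # not the "dy" defect
  expect_equal(lemmatize_token("portland", cp), "portland")
  # output is always in the corpus or equal to the input
  toks <- c("classes", "cooking", "wolves", "dies", "zzzes", "portland")
  out <- lemmatize_token(toks, cp)
  expect_true(all(out %in% cp$word | out == toks))
  # single-character roots are rejected
  cpx <- word_corpus(c("x", "i"), c(5, 5))
  expect_equal(lemmatize_token("xs", cpx), "xs")
})

test_that("clean_query composes the full procedure", {
  cp <- example_corpus()
  res <- clean_query("Where are cooking classes in Portland?", cp)
  expect_equal(res$tokens, c("where", "are", "cook", "class", "in", "portland"))
  expect_equal(res$n_corrected, 0L)
  expect_equal(clean_query("???", cp)$tokens, character(0))
  expect_equal(clean_query("Wolves!!", cp)$tokens, "wolf")
  res2 <- clean_query("wrod classs", word_corpus(c("word", "class"), c(9, 9)))
  expect_equal(res2$tokens, c("word", "class"))
  expect_equal(res2$n_corrected, 2L)
})

test_that("cleaning a table yields aligned long output and is idempotent", {
  cp <- example_corpus()
  recs <- data.frame(
    subject_id = c("a", "a", "b"),
    timestamp = as.POSIXct("2015-01-01", tz = "UTC") + 1:3,
    query = c("Cooking classes", "???", "wolves in Portland"),
    stringsAsFactors = FALSE
  )
  cl <- clean_searches(recs, cp)
  expect_equal(nrow(cl$searches), 3L)
  expect_equal(cl$searches$n_tokens, c(2L, 0L, 3L))  # empty search retained
  expect_equal(cl$tokens$token, c("cook", "class", "wolf", "in", "portland"))
  expect_equal(nrow(cl$tokens), sum(cl$searches$n_tokens))
  # re-cleaning the cleaned queries changes nothing
  requeried <- data.frame(
    subject_id = cl$searches$subject_id,
    query = vapply(split(cl$tokens$token, factor(cl$tokens$search_id,
                                                 levels = cl$searches$search_id)),
                   paste, "", collapse = " "),
    stringsAsFactors = FALSE
  )
  cl2 <- clean_searches(requeried, cp)
  expect_equal(cl2$tokens$token, cl$tokens$token)
  expect_equal(sum(cl2$tokens$corrected), 0L)
})
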