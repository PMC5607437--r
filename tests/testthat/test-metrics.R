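test_that("term frequencies count token instances across subjects", {
  cl <- toy_cleaned(list(c("cook", "class"), "cook"))
  tab <- term_frequency_table(cl)
  expect_equal(tab$counts[["cook"]], 2)
  expect_equal(tab$counts[["class"]], 1)
  expect_equal(tab$total_tokens, 3L)
  expect_equal(sum(tab$counts), tab$total_tokens)

  one <- term_frequency_table(toy_cleaned(list("a")))
  expect_equal(one$counts[["a"]], 1)

  pooled <- term_frequency_table(
    toy_cleaned(list("portland", "portland"), subjects = c("s1", "s2")))
  expect_equal(pooled$counts[["portland"]], 2)

  expect_error(term_frequency_table(toy_cleaned(list(character(0)))),
               "no tokens")
})

test_that("obscurity is the inverse cohort frequency", {
  tab <- term_frequency_table(
    toy_cleaned(list(rep("common", 4), "rare", "portland")))
  expect_equal(term_obscurity("rare", tab), 1)
  expect_equal(term_obscurity("common", tab), 0.25)
  expect_error(term_obscurity("unknown", tab), "not in frequency table")
  expect_equal(term_obscurity("unknown", tab, unseen = "one"), 1)
  # a term searched 318 times has obscurity 1/318
  big <- toy_cleaned(c(replicate(318, "portland", simplify = FALSE),
                       list("oregon")))
  expect_equal(term_obscurity("portland", term_frequency_table(big)),
               1 / 318)
})

test_that("subject profiles reproduce hand-enumerated metrics", {
  cl <- toy_cleaned(list(c("cook", "class"), c("cook", "portland")))
  pr <- subject_profiles(cl)
  expect_equal(pr$n_searches, 2)
  expect_equal(pr$words_per_search, 2.0)
  expect_equal(pr$unique_terms_per_search, 1.5)  # 3 distinct / 2 searches
  expect_equal(pr$mean_word_length, (4 + 5 + 4 + 8) / 4)
  expect_equal(pr$mean_obscurity, (0.5 + 1 + 0.5 + 1) / 4)

  single <- subject_profiles(toy_cleaned(list("a")))
  expect_equal(single$unique_terms_per_search, 1.0)
  expect_equal(single$mean_word_length, 1)

  # repetitive searcher: distinct-vocabulary definition can fall below 1
  rep4 <- toy_cleaned(replicate(4, "cook", simplify = FALSE))
  expect_equal(subject_profiles(rep4)$unique_terms_per_search, 0.25)
  expect_equal(subject_profiles(rep4,
                                unique_terms_mode = "tokens")$unique_terms_per_search,
               1.0)
})

test_that("profile invariants hold on generated cohorts", {
  st <- simulate_study(generator_config(seed = 5, n_subjects = 12))
  recs <- window_to_evaluation(filter_engine(st$records), st$clinical)
  cl <- clean_searches(recs, st$corpus)
  tab <- term_frequency_table(cl)
  pr <- subject_profiles(cl, tab)
  # conservation: subjects' tokens sum to the table total
  expect_equal(sum(pr$n_tokens), tab$total_tokens)
  expect_true(all(pr$unique_terms_per_search <= pr$words_per_search))
  expect_true(all(pr$mean_obscurity > 0 & pr$mean_obscurity <= 1))
  expect_true(all(pr$mean_word_length >= 1))
  # duplicating a subject's tokens into the table makes their terms more
  # frequent, hence less obscure
  s1 <- pr$subject_id[1]
  tok1 <- cl$tokens[cl$tokens$subject_id == s1, ]
  dup <- cl
  dup$tokens <- rbind(cl$tokens, tok1)
  tab2 <- term_frequency_table(dup)
  pr2 <- subject_profiles(cl, tab2)
  expect_lt(pr2$mean_obscurity[pr2$subject_id == s1],
            pr$mean_obscurity[pr$subject_id == s1])
})

test_that("cohort descriptives summarize the expected quantities", {
  cl <- toy_cleaned(list(c("portland", "cook"), c("portland", "class"),
                         "portland"),
                    subjects = c("s1", "s1", "s2"))
  pr <- subject_profiles(cl)
  d <- cohort_descriptives(pr, cl)
  expect_equal(d$n_subjects, 2)
  expect_equal(names(d$top_terms)[1], "portland")
  expect_equal(d$words_per_search$mean, 5 / 3)
  # single subject: medians equal that subject's values
  one <- toy_cleaned(list(c("cook", "class")))
  pr1 <- subject_profiles(one)
  d1 <- cohort_descriptives(pr1, one)
  expect_equal(d1$searches$median, pr1$n_searches)
  expect_output(print(d), "Number of searches")
})
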