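write_log <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("subject_id,timestamp,engine,query", rows), path)
  path
}

test_that("search-log parsing keeps well-formed rows and reports skips", {
  empty <- write_log(character(0))
  expect_equal(nrow(read_search_log(empty)), 0L)

  good <- write_log(c(
    "s1,2015-06-01T10:00:00,Google,cooking classes",
    "s1,2015-06-02T11:30:00,Bing,weather portland",
    "s2,2015-06-03T09:15:00,Yahoo,"
  ))
  recs <- read_search_log(good)
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$subject_id, c("s1", "s1", "s2"))
  expect_equal(recs$query[3], "")  # empty query is legal
  expect_s3_class(recs$timestamp, "POSIXct")

  bad <- write_log(c(
    "s1,2015-06-01T10:00:00,Google,ok row",
    "s1,not-a-date,Google,bad row"
  ))
  expect_warning(recs <- read_search_log(bad), "skipped 1")
  expect_equal(nrow(recs), 1L)
  expect_equal(attr(recs, "n_skipped"), 1L)

  expect_error(read_search_log(tempfile()), "not found")
  noqcol <- tempfile(fileext = ".csv")
  writeLines("subject_id,timestamp,engine", noqcol)
  expect_error(read_search_log(noqcol), "missing declared column")
})

test_that("engine filter keeps the four major engines under label variants", {
  recs <- data.frame(
    subject_id = "s1", timestamp = as.POSIXct("2015-06-01", tz = "UTC"),
    engine = c("google", "target.com", "bing", "Ask.com", "facebook.com",
               "https://search.yahoo.com/search", "www.google.co.uk",
               "Yahoo"),
    query = "q", stringsAsFactors = FALSE
  )
  kept <- filter_engine(recs)
  expect_equal(kept$engine,
               c("google", "bing", "Ask.com", "https://search.yahoo.com/search",
                 "www.google.co.uk", "Yahoo"))
  # order preserved, no duplication, idempotent
  expect_equal(filter_engine(kept), kept)
  expect_lte(nrow(kept), nrow(recs))
  # all-nonmajor input empties out
  fb <- recs[recs$engine == "facebook.com", ]
  expect_equal(nrow(filter_engine(fb)), 0L)
})

test_that("evaluation window keeps records within 91 days and flags excluded subjects", {
  clinical <- data.frame(
    subject_id = c("s1", "s2"), age = c(75, 80),
    sex = c("female", "male"), education = c(16, 12),
    evaluation_date = as.Date("2015-06-01"), stringsAsFactors = FALSE
  )
  recs <- data.frame(
    subject_id = c("s1", "s1", "s1", "s2"),
    timestamp = as.POSIXct(c("2015-05-02 10:00:00",   # 30 d before
                             "2015-09-09 10:00:00",   # 100 d after
                             "2015-08-31 23:00:00",   # 91 d after
                             "2016-01-01 10:00:00"),  # far outside
                           tz = "UTC"),
    engine = "google", query = "q", stringsAsFactors = FALSE
  )
  out <- window_to_evaluation(recs, clinical, window_days = 91)
  expect_equal(nrow(out), 2L)
  expect_equal(unique(out$subject_id), "s1")
  expect_equal(attr(out, "excluded_subjects"), "s2")
  # idempotent
  again <- window_to_evaluation(out, clinical, window_days = 91)
  expect_equal(again$timestamp, out$timestamp)
  # unknown subject is an error naming it
  recs$subject_id[1] <- "ghost"
  expect_error(window_to_evaluation(recs, clinical), "ghost")
})

test_that("clinical table reader validates required columns", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,age,sex,education,evaluation_date,digit_symbol",
               "s1,77,Female,14,2015-06-01,43"), p)
  cl <- read_clinical_table(p)
  expect_equal(cl$sex, "female")
  expect_equal(attr(cl, "test_cols"), "digit_symbol")
  writeLines(c("subject_id,age", "s1,77"), p)
  expect_error(read_clinical_table(p), "missing column")
})
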