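# Composite cognitive z-scores from raw neuropsychological test scores,
# normed on a cognitively intact reference cohort.

#' Default neuropsychological battery with synthetic reference norms
#'
#' The battery covers five cognitive domains with two or three
#' representative tests each: working memory (Letter-Number Sequencing,
#' Digit Span Backward), attention/processing speed (Digit Span Forward,
#' Digit Symbol, Trail Making A), memory (Logical Memory II, Visual
#' Reproduction II, Word-List Recall), executive function (CFL letter
#' fluency, Trail Making B, Stroop), and visuospatial function (Block
#' Design, Picture Completion, Visual Reproduction I). Timed tests
#' (Trail Making A/B) carry direction -1: longer times mean worse
#' performance, so their z-scores are sign-flipped to keep "higher is
#' better" throughout.
#'
#' The `mean`/`sd` values here are synthetic placeholders in plausible
#' raw-score units; real analyses must supply norms estimated from their
#' own cognitively intact reference cohort via [read_norms()].
#'
#' @return A data frame with columns `test`, `domain`, `mean`, `sd`,
#'   `direction`.
#' @export
default_norms <- function() {
  data.frame(
    test = c("letter_number_sequencing", "digit_span_backward",
             "digit_span_forward", "digit_symbol", "trail_making_a",
             "logical_memory_ii", "visual_reproduction_ii",
             "word_list_recall",
             "letter_fluency_cfl", "trail_making_b", "stroop",
             "block_design", "picture_completion", "visual_reproduction_i"),
    domain = c("working_memory", "working_memory",
               "attention_processing_speed", "attention_processing_speed",
               "attention_processing_speed",
               "memory", "memory", "memory",
               "executive_function", "executive_function",
               "executive_function",
               "visuospatial", "visuospatial", "visuospatial"),
    mean = c(10.5, 4.8, 6.6, 45, 42, 12.5, 15.5, 6.8,
             38, 105, 28, 25, 14, 27),
    sd = c(2.5, 1.2, 1.1, 11, 15, 4.0, 6.5, 1.8,
           11, 45, 7.5, 7, 3.5, 7),
    direction = c(1, 1, 1, 1, -1, 1, 1, 1, 1, -1, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Read a reference-norms table
#'
#' @param path CSV with columns `test`, `domain`, `mean`, `sd`,
#'   `direction` (+1 higher-is-better, -1 higher-is-worse).
#' @return A validated norms data frame.
#' @export
read_norms <- function(path) {
  if (!file.exists(path)) stop("norms file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("test", "domain", "mean", "sd", "direction")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("norms table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  validate_norms(x)
}

validate_norms <- function(norms) {
  if (any(norms$sd <= 0)) stop("all norm SDs must be > 0")
  if (!all(norms$direction %in% c(-1, 1)))
    stop("direction must be +1 or -1")
  if (anyDuplicated(norms$test))
    stop("duplicated test in norms table")
  norms
}

#' z-score a raw test score against its reference norm
#'
#' `z = direction * (raw - mean) / sd`, so a score one reference SD
#' better than the intact-cohort mean is +1 regardless of whether the
#' raw scale runs up (most tests) or down (timed tests).
#'
#' @param raw Numeric raw score(s).
#' @param mean,sd Reference mean and SD (from the intact cohort); `sd > 0`.
#' @param direction +1 if higher raw scores are better, -1 if worse.
#' @return Numeric z-score(s).
#' @export
test_zscore <- function(raw, mean, sd, direction = 1) {
  if (any(sd <= 0)) stop("norm sd must be > 0")
  direction * (raw - mean) / sd
}

#' Composite cognitive z-score for one subject
#'
#' z-normalizes every available test against its norm and averages.
#' Default mode `"tests"` is the unweighted mean over tests; mode
#' `"domains"` first averages within each cognitive domain, then across
#' the five domain means (equal domain weighting). Missing tests are
#' skipped; the number skipped is attached as attribute `n_missing`.
#'
#' @param scores Named numeric vector of raw scores (names are test
#'   names). `NA` entries are treated as missing.
#' @param norms A norms table (see [default_norms()]).
#' @param mode `"tests"` or `"domains"`.
#' @return The composite z (numeric scalar) with attributes `per_test_z`
#'   and `n_missing`.
#' @export
composite_zscore <- function(scores, norms = default_norms(),
                             mode = c("tests", "domains")) {
  mode <- match.arg(mode)
  validate_norms(norms)
  scores <- scores[!is.na(scores)]
  if (!length(scores)) stop("no available test scores for subject")
  idx <- match(names(scores), norms$test)
  if (anyNA(idx))
    stop("no norm for test(s): ",
         paste(names(scores)[is.na(idx)], collapse = ", "))
  z <- test_zscore(as.numeric(scores), norms$mean[idx], norms$sd[idx],
                   norms$direction[idx])
  names(z) <- names(scores)
  n_missing <- sum(!norms$test %in% names(scores))
  comp <- if (mode == "tests") {
    mean(z)
  } else {
    mean(tapply(z, norms$domain[idx], mean))
  }
  structure(comp, per_test_z = z, n_missing = n_missing)
}

#' Composite cognitive z-scores for a cohort
#'
#' @param clinical A wide data frame with `subject_id` and one column per
#'   raw test score (see [read_clinical_table()]); non-test columns are
#'   ignored.
#' @param norms A norms table.
#' @param mode Passed to [composite_zscore()].
#' @return Data frame with `subject_id` and `cognitive_z`.
#' @export
composite_scores <- function(clinical, norms = default_norms(),
                             mode = "tests") {
  test_cols <- intersect(norms$test, names(clinical))
  if (!length(test_cols))
    stop("clinical table contains none of the normed tests")
  z <- vapply(seq_len(nrow(clinical)), function(i) {
    s <- unlist(clinical[i, test_cols])
    as.numeric(composite_zscore(s, norms, mode))
  }, 0)
  data.frame(subject_id = clinical$subject_id, cognitive_z = z,
             stringsAsFactors = FALSE)
}
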