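# Cohort term-frequency table, inverse-frequency obscurity, and the three
# per-subject lexical metrics used as regression predictors.

#' Tabulate term frequencies across all subjects
#'
#' Counts token instances (repeats within a search count) across every
#' cleaned search in the analysis window, pooled over subjects. This
#' within-dataset table defines term obscurity.
#'
#' @param cleaned A `cleaned_searches` object or a long token data frame
#'   with a `token` column.
#' @return An object of class `term_frequency`: list with `counts`
#'   (named numeric vector, term -> count) and `total_tokens`.
#' @export
term_frequency_table <- function(cleaned) {
  tokens <- if (inherits(cleaned, "cleaned_searches")) cleaned$tokens$token
            else cleaned$token
  tokens <- tokens[!is.na(tokens) & nzchar(tokens)]
  if (!length(tokens)) stop("no tokens to tabulate")
  tab <- table(tokens)
  counts <- as.numeric(tab)
  names(counts) <- names(tab)
  structure(list(counts = counts, total_tokens = length(tokens)),
            class = "term_frequency")
}

#' @export
print.term_frequency <- function(x, ...) {
  cat("<term_frequency> ", length(x$counts), " distinct terms, ",
      x$total_tokens, " token instances\n", sep = "")
  invisible(x)
}

#' Term obscurity: inverse cohort frequency
#'
#' The obscurity of a term is 1 divided by the number of times it was
#' searched for across all subjects; a term searched once has obscurity
#' 1, a very common term approaches 0.
#'
#' @param terms Character vector of terms.
#' @param table A [term_frequency_table()].
#' @param unseen `"error"` (default) to fail on a term absent from the
#'   table; `"one"` to score unseen terms as maximally obscure (used when
#'   scoring against an external table).
#' @return Numeric vector of obscurities in (0, 1].
#' @export
term_obscurity <- function(terms, table, unseen = c("error", "one")) {
  unseen <- match.arg(unseen)
  stopifnot(inherits(table, "term_frequency"))
  f <- table$counts[match(terms, names(table$counts))]
  if (anyNA(f)) {
    if (unseen == "error")
      stop("term(s) not in frequency table: ",
           paste(utils::head(unique(terms[is.na(f)]), 5), collapse = ", "))
    f[is.na(f)] <- 1
  }
  unname(1 / f)
}

#' Per-subject lexical profiles
#'
#' Computes, for every subject with at least one cleaned token, the three
#' regression predictors plus descriptives:
#' * `words_per_search`: total tokens divided by searches;
#' * `unique_terms_per_search`: by default the size of the subject's
#'   distinct vocabulary divided by searches (`"distinct_vocab"`), which
#'   can fall below 1 for repetitive searchers; `"tokens"` gives the
#'   literal tokens-over-searches reading;
#' * `mean_word_length`: total letters over total tokens;
#' * `mean_obscurity`: mean inverse cohort frequency, by default over
#'   token instances (`"instances"`), optionally over the subject's
#'   distinct terms (`"types"`).
#'
#' @param cleaned A `cleaned_searches` object.
#' @param table A [term_frequency_table()]; defaults to the table built
#'   from `cleaned` itself (the within-dataset definition). Supply an
#'   external table to break that circularity.
#' @param unique_terms_mode `"distinct_vocab"` or `"tokens"`.
#' @param obscurity_over `"instances"` or `"types"`.
#' @param unseen Passed to [term_obscurity()] (relevant for external
#'   tables).
#' @return A data frame, one row per subject, with columns `subject_id`,
#'   `n_searches`, `n_tokens`, `words_per_search`,
#'   `unique_terms_per_search`, `mean_word_length`, `mean_obscurity`.
#'   Zero-token subjects are excluded with a warning.
#' @export
subject_profiles <- function(cleaned, table = NULL,
                             unique_terms_mode = c("distinct_vocab", "tokens"),
                             obscurity_over = c("instances", "types"),
                             unseen = "error") {
  stopifnot(inherits(cleaned, "cleaned_searches"))
  unique_terms_mode <- match.arg(unique_terms_mode)
  obscurity_over <- match.arg(obscurity_over)
  if (is.null(table)) table <- term_frequency_table(cleaned)
  tok <- cleaned$tokens
  searches <- cleaned$searches
  n_searches <- tapply(rep(1L, nrow(searches)), searches$subject_id, sum)
  subjects <- names(n_searches)
  by_subj <- split(tok$token, factor(tok$subject_id, levels = subjects))
  empty <- vapply(by_subj, length, 0L) == 0L
  if (any(empty)) {
    warning("excluding ", sum(empty), " subject(s) with zero cleaned tokens: ",
            paste(subjects[empty], collapse = ", "))
    subjects <- subjects[!empty]
    by_subj <- by_subj[!empty]
    n_searches <- n_searches[!empty]
  }
  prof <- lapply(seq_along(subjects), function(i) {
    tk <- by_subj[[i]]
    ns <- as.numeric(n_searches[[i]])
    obs <- term_obscurity(if (obscurity_over == "instances") tk else unique(tk),
                          table, unseen = unseen)
    data.frame(
      subject_id = subjects[i],
      n_searches = ns,
      n_tokens = length(tk),
      words_per_search = length(tk) / ns,
      unique_terms_per_search =
        (if (unique_terms_mode == "distinct_vocab") length(unique(tk))
         else length(tk)) / ns,
      mean_word_length = sum(nchar(tk)) / length(tk),
      mean_obscurity = mean(obs),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, prof)
  rownames(out) <- NULL
  out
}

#' Cohort descriptive statistics
#'
#' Summaries mirroring a descriptives table: median and IQR of per-subject
#' search counts, mean and SD of words per search (over searches), letters
#' per word (over tokens) and per-subject obscurity, min-max ranges, and
#' the most frequent terms.
#'
#' @param profiles Output of [subject_profiles()].
#' @param cleaned The `cleaned_searches` object the profiles came from.
#' @param table Optional [term_frequency_table()] for the top-term list.
#' @param top_k How many top terms to report.
#' @return An object of class `cohort_descriptives` (a list) with a print
#'   method.
#' @export
cohort_descriptives <- function(profiles, cleaned, table = NULL, top_k = 10) {
  stopifnot(nrow(profiles) >= 1)
  if (is.null(table)) table <- term_frequency_table(cleaned)
  tok <- cleaned$tokens$token
  per_search <- cleaned$searches$n_tokens
  lens <- nchar(tok)
  top <- sort(table$counts, decreasing = TRUE)
  top <- utils::head(top, top_k)
  out <- list(
    n_subjects = nrow(profiles),
    n_searches = sum(profiles$n_searches),
    n_tokens = table$total_tokens,
    searches = list(median = stats::median(profiles$n_searches),
                    iqr = stats::IQR(profiles$n_searches),
                    range = range(profiles$n_searches)),
    words_per_search = list(mean = mean(per_search), sd = stats::sd(per_search),
                            range = range(per_search)),
    letters_per_word = list(mean = mean(lens), sd = stats::sd(lens),
                            range = range(lens)),
    obscurity = list(mean = mean(profiles$mean_obscurity),
                     sd = stats::sd(profiles$mean_obscurity),
                     range = range(profiles$mean_obscurity)),
    unique_terms = list(mean = mean(profiles$unique_terms_per_search),
                        range = range(profiles$unique_terms_per_search)),
    top_terms = top
  )
  class(out) <- "cohort_descriptives"
  out
}

#' @export
print.cohort_descriptives <- function(x, digits = 3, ...) {
  f <- function(v) format(round(v, digits), trim = TRUE)
  cat("Cohort descriptives (", x$n_subjects, " subjects, ",
      x$n_searches, " searches, ", x$n_tokens, " tokens)\n", sep = "")
  cat(sprintf("  Number of searches, median (IQR): %s (%s)   range %s-%s\n",
              f(x$searches$median), f(x$searches$iqr),
              f(x$searches$range[1]), f(x$searches$range[2])))
  cat(sprintf("  Words per search,   mean (SD):    %s (%s)   range %s-%s\n",
              f(x$words_per_search$mean), f(x$words_per_search$sd),
              f(x$words_per_search$range[1]), f(x$words_per_search$range[2])))
  cat(sprintf("  Letters per word,   mean (SD):    %s (%s)   range %s-%s\n",
              f(x$letters_per_word$mean), f(x$letters_per_word$sd),
              f(x$letters_per_word$range[1]), f(x$letters_per_word$range[2])))
  cat(sprintf("  Word obscurity,     mean (SD):    %s (%s)   range %s-%s\n",
              f(x$obscurity$mean), f(x$obscurity$sd),
              f(x$obscurity$range[1]), f(x$obscurity$range[2])))
  cat("  Top terms: ",
      paste(sprintf("%s (n=%d)", names(x$top_terms),
                    as.integer(x$top_terms)), collapse = ", "), "\n", sep = "")
  invisible(x)
}
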