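# Query cleaning: ASCII normalization -> tokenization -> corpus-based
# spell correction -> dictionary-validated lemmatization.

# Accented (precomposed Latin-1/Latin-2) letters -> ASCII. Base R has no
# Unicode compatibility decomposition, so the mapping is explicit; anything
# not covered (and not printable ASCII) is treated as unreadable and dropped.
# Built pairwise so the two chartr() strings stay in lockstep.
.accent_pairs <- c(
  "àa", "áa", "âa", "ãa", "äa", "åa",
  "āa", "ăa", "ąa",
  "çc", "ćc", "ĉc", "čc",
  "ďd", "đd",
  "èe", "ée", "êe", "ëe", "ēe", "ĕe",
  "ėe", "ęe", "ěe",
  "ĝg", "ğg", "ġg",
  "ìi", "íi", "îi", "ïi", "ĩi", "īi",
  "ĭi", "įi", "ıi",
  "ĺl", "ľl", "łl",
  "ñn", "ńn", "ňn",
  "òo", "óo", "ôo", "õo", "öo", "øo",
  "ōo", "ŏo", "őo",
  "ŕr", "řr",
  "śs", "ŝs", "şs", "šs",
  "ţt", "ťt",
  "ùu", "úu", "ûu", "üu", "ũu", "ūu",
  "ŭu", "ůu", "űu", "ųu",
  "ýy", "ÿy",
  "źz", "żz", "žz",
  "Àa", "Áa", "Âa", "Ãa", "Äa", "Åa",
  "Çc",
  "Èe", "Ée", "Êe", "Ëe",
  "Ìi", "Íi", "Îi", "Ïi",
  "Ñn",
  "Òo", "Óo", "Ôo", "Õo", "Öo", "Øo",
  "Ùu", "Úu", "Ûu", "Üu",
  "Ýy",
  "Őo", "Űu"
)
.accent_from <- paste(substr(.accent_pairs, 1L, 1L), collapse = "")
.accent_to <- paste(substr(.accent_pairs, 2L, 2L), collapse = "")

#' Normalize a raw query string to clean ASCII
#'
#' Lowercases, transliterates accented Latin letters to their ASCII
#' equivalents (for example u with double acute becomes `u`), removes
#' punctuation and any remaining unreadable (non-ASCII) characters, and
#' collapses whitespace runs to single spaces. The result contains only
#' lowercase letters, digits and single spaces. Punctuation is removed,
#' not treated as a separator, so hyphenated forms join.
#'
#' @param raw Character vector of raw query strings.
#' @return Character vector of normalized strings (possibly empty).
#' @examples
#' normalize_query("Where are cooking classes in Portland?")
#' @export
normalize_query <- function(raw) {
  x <- enc2utf8(as.character(raw))
  x[is.na(x)] <- ""
  x <- chartr(.accent_from, .accent_to, x)
  x <- tolower(x)
  # whitespace (incl. tabs/newlines) separates; everything else non-ASCII
  # or punctuation is unreadable/punctuation and is deleted in place
  x <- gsub("[\\s]+", " ", x, perl = TRUE)
  x <- gsub("[^a-z0-9 ]", "", x, perl = TRUE, useBytes = FALSE)
  x <- gsub(" +", " ", x)
  trimws(x)
}

#' Split a normalized query into unigram tokens
#'
#' @param normalized Character vector of already-normalized strings
#'   (see [normalize_query()]).
#' @return For a single string, a character vector of tokens; for a vector,
#'   a list of token vectors. Empty tokens are discarded; order preserved.
#' @export
tokenize_query <- function(normalized) {
  out <- strsplit(normalized, " ", fixed = TRUE)
  out <- lapply(out, function(t) t[nzchar(t)])
  if (length(out) == 1L) out[[1L]] else out
}

# candidate generators for the three correction tiers
.deletions <- function(token) {
  n <- nchar(token)
  if (n < 2L) return(character(0))
  vapply(seq_len(n), function(i)
    paste0(substr(token, 1L, i - 1L), substr(token, i + 1L, n)), "")
}

.transpositions <- function(token) {
  n <- nchar(token)
  if (n < 2L) return(character(0))
  ch <- strsplit(token, "", fixed = TRUE)[[1L]]
  out <- character(n - 1L)
  for (i in seq_len(n - 1L)) {
    sw <- ch
    sw[c(i, i + 1L)] <- sw[c(i + 1L, i)]
    out[i] <- paste(sw, collapse = "")
  }
  unique(out)
}

.insertions <- function(token) {
  n <- nchar(token)
  pre <- substring(token, 0L, 0:n)
  post <- substring(token, 1:(n + 1L), n)
  as.vector(t(outer(seq_len(n + 1L), letters,
                    function(i, l) paste0(pre[i], l, post[i]))))
}

.best_candidate <- function(cands, corpus) {
  idx <- match(cands, corpus$word)
  hit <- !is.na(idx)
  if (!any(hit)) return(NA_character_)
  w <- cands[hit]
  f <- corpus$count[idx[hit]]
  # highest frequency, ties broken lexicographically
  w <- w[order(-f, w, method = "radix")]
  w[1L]
}

#' Correct the spelling of query tokens against a word corpus
#'
#' A token already in the corpus (or purely numeric) is returned unchanged.
#' Otherwise candidates are generated in three tiers, tried in order:
#' single-letter deletions, adjacent transpositions, single-letter
#' insertions (a-z at every position). The first tier containing any
#' in-corpus candidate supplies the correction; among candidates in that
#' tier the one with the highest corpus frequency wins, ties broken
#' lexicographically. If no tier hits, the token is left as is. Letter
#' substitutions are deliberately not attempted.
#'
#' @param tokens Character vector of lowercase ASCII tokens.
#' @param corpus A [word_corpus()].
#' @return Character vector of corrected tokens, same length as `tokens`.
#' @examples
#' cp <- word_corpus(c("word", "class", "lass"), c(50, 10, 1))
#' spell_correct(c("wrod", "classs", "qzxv"), cp)
#' @export
spell_correct <- function(tokens, corpus) {
  stopifnot(inherits(corpus, "word_corpus"))
  out <- tokens
  skip <- corpus_has(tokens, corpus) | grepl("^[0-9]+$", tokens) | !nzchar(tokens)
  todo <- which(!skip)
  if (!length(todo)) return(out)
  # correct each distinct unknown token once
  uniq <- unique(tokens[todo])
  corrected <- vapply(uniq, function(tok) {
    for (gen in list(.deletions, .transpositions, .insertions)) {
      best <- .best_candidate(gen(tok), corpus)
      if (!is.na(best)) return(best)
    }
    tok
  }, "", USE.NAMES = TRUE)
  out[todo] <- unname(corrected[match(tokens[todo], uniq)])
  out
}

#' The default suffix rule table for lemmatization
#'
#' Ordered suffix substitutions tried by [lemmatize_token()]; the first
#' rule whose result is a corpus word wins.
#'
#' @return A data frame with columns `suffix` and `replacement`.
#' @export
default_suffix_rules <- function() {
  data.frame(
    suffix = c("ies", "es", "s", "ing", "ing", "ed", "ed", "ves"),
    replacement = c("y", "", "", "", "e", "", "e", "f"),
    stringsAsFactors = FALSE
  )
}

#' Reduce tokens to dictionary-validated root forms
#'
#' Applies ordered suffix substitution rules and returns the first
#' candidate root that exists in the corpus; if no rule yields a corpus
#' word the token is returned unchanged. Single-character results are
#' rejected, and purely numeric tokens pass through.
#'
#' @param tokens Character vector of lowercase ASCII tokens.
#' @param corpus A [word_corpus()] used to validate candidate roots.
#' @param rules A rule table as from [default_suffix_rules()].
#' @return Character vector of lemmas, same length as `tokens`.
#' @examples
#' cp <- word_corpus(c("class", "cook", "wolf", "die"))
#' lemmatize_token(c("classes", "cooking", "wolves", "dies"), cp)
#' @export
lemmatize_token <- function(tokens, corpus, rules = default_suffix_rules()) {
  stopifnot(inherits(corpus, "word_corpus"))
  uniq <- unique(tokens)
  lem <- vapply(uniq, function(tok) {
    if (grepl("^[0-9]+$", tok) || !nzchar(tok)) return(tok)
    n <- nchar(tok)
    for (r in seq_len(nrow(rules))) {
      suf <- rules$suffix[r]
      ns <- nchar(suf)
      if (n <= ns) next
      if (substring(tok, n - ns + 1L, n) != suf) next
      cand <- paste0(substring(tok, 1L, n - ns), rules$replacement[r])
      if (nchar(cand) < 2L) next
      if (corpus_has(cand, corpus)) return(cand)
    }
    tok
  }, "", USE.NAMES = TRUE)
  unname(lem[match(tokens, uniq)])
}

#' Clean one raw query
#'
#' Composes the full cleaning procedure: normalization, tokenization,
#' spell correction, lemmatization.
#'
#' @param raw A single raw query string.
#' @param corpus A [word_corpus()].
#' @param rules Suffix rules for lemmatization.
#' @return A list with `raw_tokens` (pre-correction), `tokens`
#'   (corrected and lemmatized) and `n_corrected` (tokens altered by
#'   spell correction). A query reduced to nothing yields empty vectors.
#' @examples
#' cp <- word_corpus(c("where", "are", "cooking", "cook", "class",
#'                     "classes", "in", "portland"))
#' clean_query("Where are cooking classes in Portland?", cp)
#' @export
clean_query <- function(raw, corpus, rules = default_suffix_rules()) {
  stopifnot(length(raw) == 1L)
  raw_tokens <- tokenize_query(normalize_query(raw))
  if (!length(raw_tokens))
    return(list(raw_tokens = character(0), tokens = character(0),
                n_corrected = 0L))
  corrected <- spell_correct(raw_tokens, corpus)
  tokens <- lemmatize_token(corrected, corpus, rules)
  list(raw_tokens = raw_tokens, tokens = tokens,
       n_corrected = sum(corrected != raw_tokens))
}

#' Clean a table of search records
#'
#' Vectorized cleaning of a search log. Searches whose queries reduce to
#' zero tokens are retained in the per-search table and flagged by
#' `n_tokens == 0`.
#'
#' @param records Data frame with columns `subject_id`, `timestamp` and
#'   `query` (as returned by [read_search_log()]).
#' @param corpus A [word_corpus()].
#' @param rules Suffix rules for lemmatization.
#' @return An object of class `cleaned_searches`: a list with
#'   * `tokens`: long data frame (`subject_id`, `search_id`, `timestamp`,
#'     `token_index`, `raw_token`, `token`, `corrected`);
#'   * `searches`: one row per input search (`search_id`, `subject_id`,
#'     `timestamp`, `n_tokens`, `n_corrected`).
#' @export
clean_searches <- function(records, corpus, rules = default_suffix_rules()) {
  stopifnot(is.data.frame(records),
            all(c("subject_id", "query") %in% names(records)))
  n <- nrow(records)
  ts <- if ("timestamp" %in% names(records)) records$timestamp else rep(NA, n)
  raw_tok <- lapply(strsplit(normalize_query(records$query), " ", fixed = TRUE),
                    function(t) t[nzchar(t)])
  lens <- lengths(raw_tok)
  flat_raw <- unlist(raw_tok, use.names = FALSE)
  if (length(flat_raw)) {
    flat_corr <- spell_correct(flat_raw, corpus)
    flat_tok <- lemmatize_token(flat_corr, corpus, rules)
  } else {
    flat_corr <- flat_tok <- character(0)
  }
  search_id <- rep.int(seq_len(n), lens)
  tokens <- data.frame(
    subject_id = records$subject_id[search_id],
    search_id = search_id,
    timestamp = ts[search_id],
    token_index = sequence(lens),
    raw_token = flat_raw,
    token = flat_tok,
    corrected = flat_corr != flat_raw,
    stringsAsFactors = FALSE
  )
  searches <- data.frame(
    search_id = seq_len(n),
    subject_id = records$subject_id,
    timestamp = ts,
    n_tokens = lens,
    n_corrected = as.integer(tapply(c(tokens$corrected, FALSE),
                                    c(search_id, n + 1L), sum)[seq_len(n)]),
    stringsAsFactors = FALSE
  )
  searches$n_corrected[is.na(searches$n_corrected)] <- 0L
  structure(list(tokens = tokens, searches = searches),
            class = "cleaned_searches")
}

#' @export
print.cleaned_searches <- function(x, ...) {
  cat("<cleaned_searches> ", nrow(x$searches), " searches, ",
      nrow(x$tokens), " tokens, ",
      length(unique(x$searches$subject_id)), " subjects; ",
      sum(x$tokens$corrected), " tokens spell-corrected\n", sep = "")
  invisible(x)
}
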