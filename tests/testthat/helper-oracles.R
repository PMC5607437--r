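# Independent oracles and small fixtures used across test files.

# Exhaustive spell-correction oracle, implemented independently of the
# package: enumerate every candidate in each tier with nested loops,
# filter by corpus membership, stop at the first tier with any hit, and
# break ties by (frequency desc, word asc).
oracle_spell <- function(token, corpus) {
  lookup <- stats::setNames(corpus$count, corpus$word)
  if (!is.na(lookup[token]) || grepl("^[0-9]+$", token)) return(token)
  ch <- strsplit(token, "")[[1]]
  n <- length(ch)
  tiers <- list()
  del <- character(0)
  if (n >= 2) for (i in 1:n) del <- c(del, paste(ch[-i], collapse = ""))
  tiers[[1]] <- del
  tr <- character(0)
  if (n >= 2) for (i in 1:(n - 1)) {
    s <- ch; tmp <- s[i]; s[i] <- s[i + 1]; s[i + 1] <- tmp
    tr <- c(tr, paste(s, collapse = ""))
  }
  tiers[[2]] <- tr
  ins <- character(0)
  for (i in 0:n) for (l in letters)
    ins <- c(ins, paste(c(ch[seq_len(i)], l, ch[seq_len(n - i) + i]),
                        collapse = ""))
  tiers[[3]] <- ins
  for (cand in tiers) {
    hits <- cand[!is.na(lookup[cand])]
    if (length(hits)) {
      hits <- unique(hits)
      f <- lookup[hits]
      ord <- order(-f, hits, method = "radix")
      return(hits[ord[1]])
    }
  }
  token
}

# Normal-equation OLS oracle: beta = (X'X)^{-1} X'y
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# A small English corpus covering the worked examples.
example_corpus <- function() {
  word_corpus(
    c("where", "are", "cooking", "cook", "class", "classes", "in",
      "portland", "wolf", "die", "word", "oregon", "photo", "how",
      "email"),
    c(500, 900, 120, 150, 200, 90, 1000, 60, 15, 80, 300, 50, 70, 400, 45))
}

# Random lowercase word
rand_word <- function(len) paste(sample(letters, len, replace = TRUE),
                                 collapse = "")

# Apply one random recoverable corruption (deletion / transposition /
# insertion) to a word.
corrupt_once <- function(w) {
  L <- nchar(w)
  op <- sample(3, 1)
  ch <- strsplit(w, "")[[1]]
  if (op == 1 && L >= 3) {
    paste(ch[-sample(L, 1)], collapse = "")
  } else if (op == 2 && L >= 2) {
    i <- sample(L - 1, 1)
    ch[c(i, i + 1)] <- ch[c(i + 1, i)]
    paste(ch, collapse = "")
  } else {
    i <- sample(L + 1, 1) - 1
    paste(c(ch[seq_len(i)], sample(letters, 1), ch[seq_len(L - i) + i]),
          collapse = "")
  }
}

# Small cleaned_searches-like structure from a list of token vectors
# (one element per search), for metric/network tests.
toy_cleaned <- function(token_lists, subjects = NULL) {
  n <- length(token_lists)
  if (is.null(subjects)) subjects <- rep("s1", n)
  lens <- lengths(token_lists)
  flat <- unlist(token_lists)
  if (is.null(flat)) flat <- character(0)
  tokens <- data.frame(
    subject_id = rep(subjects, lens),
    search_id = rep(seq_len(n), lens),
    timestamp = rep(NA, sum(lens)),
    token_index = sequence(lens),
    raw_token = flat,
    token = flat,
    corrected = rep(FALSE, sum(lens)),
    stringsAsFactors = FALSE
  )
  searches <- data.frame(
    search_id = seq_len(n), subject_id = subjects, timestamp = NA,
    n_tokens = lens, n_corrected = 0L, stringsAsFactors = FALSE
  )
  structure(list(tokens = tokens, searches = searches),
            class = "cleaned_searches")
}
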