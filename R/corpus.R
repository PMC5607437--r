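#' Construct a word-frequency corpus
#'
#' A word corpus is the dictionary against which spell correction and
#' lemmatization are validated: a table of lowercase ASCII words with
#' positive occurrence counts. Lookup is exact-match.
#'
#' @param words Character vector of lowercase ASCII words (no whitespace).
#' @param counts Integer vector of occurrence counts, all >= 1. Recycled if
#'   length 1.
#' @return An object of class `word_corpus`: a data frame with columns
#'   `word` and `count`.
#' @examples
#' word_corpus(c("cook", "cooking", "class"), c(50, 30, 40))
#' @export
word_corpus <- function(words, counts = 1L) {
  words <- as.character(words)
  counts <- as.numeric(counts)
  if (length(counts) == 1L) counts <- rep(counts, length(words))
  if (length(counts) != length(words))
    stop("`words` and `counts` must have the same length")
  if (anyNA(words) || any(words == ""))
    stop("corpus words must be non-empty and non-missing")
  if (any(grepl("[^a-z0-9']", words)))
    stop("corpus words must be lowercase ASCII")
  if (any(counts < 1)) stop("all corpus counts must be >= 1")
  dup <- duplicated(words)
  if (any(dup)) {
    counts <- as.vector(tapply(counts, factor(words, levels = unique(words)), sum))
    words <- unique(words)
  }
  structure(data.frame(word = words, count = counts,
                       stringsAsFactors = FALSE),
            class = c("word_corpus", "data.frame"))
}

#' Read a word corpus from a two-column text file
#'
#' Format: one `word<TAB>count` pair per line; lines starting with `#` are
#' comments. Words are lowercased on read.
#'
#' @param path Path to a plain-text corpus file.
#' @return A [word_corpus()] object.
#' @export
read_word_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("corpus file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) stop("malformed corpus line(s): ", paste(which(bad)[1], collapse = ", "))
  words <- tolower(vapply(parts, `[[`, "", 1L))
  counts <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(counts)) stop("non-numeric count in corpus file: ", path)
  word_corpus(words, counts)
}

#' Write a word corpus to a two-column text file
#'
#' @param corpus A [word_corpus()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_word_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "word_corpus"))
  writeLines(c("# word\tcount",
               paste(corpus$word, format(corpus$count, scientific = FALSE,
                                         trim = TRUE), sep = "\t")),
             path)
  invisible(path)
}

#' The bundled default English corpus
#'
#' A compact curated list of common English words (function words plus
#' frequent nouns, verbs and their inflections) with synthetic, Zipf-like
#' indicative counts. It is a small stand-in for the large reference corpus
#' a production analysis would plug in via [read_word_corpus()]; the counts
#' are invented and only their ordering matters (spell-correction
#' tie-breaks).
#'
#' @return A [word_corpus()] object.
#' @export
default_corpus <- function() {
  path <- system.file("extdata", "english_wordlist_synthetic_counts.tsv",
                      package = "searchlex")
  if (path == "") stop("bundled corpus not found; is the package installed?")
  read_word_corpus(path)
}

# fast membership / count lookup (hashed via match)
corpus_has <- function(tokens, corpus) {
  !is.na(match(tokens, corpus$word))
}

corpus_count <- function(tokens, corpus) {
  corpus$count[match(tokens, corpus$word)]
}

#' @export
print.word_corpus <- function(x, ...) {
  cat("<word_corpus> ", nrow(x), " words, total count ",
      format(sum(x$count), scientific = FALSE), "\n", sep = "")
  invisible(x)
}
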