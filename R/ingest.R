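# Reading search logs and clinical tables; engine and evaluation-window
# filters.

#' Default log dialect
#'
#' Column names and timestamp formats expected in a search-log file.
#' Timestamps default to ISO-8601 (`2015-06-01T10:30:00` or with a space).
#'
#' @param subject,timestamp,engine,query Column names in the file.
#' @param formats Candidate `strptime` formats tried in order.
#' @param tz Time zone used for parsing.
#' @return A named list describing the dialect.
#' @export
log_dialect <- function(subject = "subject_id", timestamp = "timestamp",
                        engine = "engine", query = "query",
                        formats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                    "%Y-%m-%d"),
                        tz = "UTC") {
  list(subject = subject, timestamp = timestamp, engine = engine,
       query = query, formats = formats, tz = tz)
}

.parse_ts <- function(x, dialect) {
  out <- rep(as.POSIXct(NA), length(x))
  left <- seq_along(x)
  for (fmt in dialect$formats) {
    if (!length(left)) break
    p <- as.POSIXct(x[left], format = fmt, tz = dialect$tz)
    ok <- !is.na(p)
    out[left[ok]] <- p[ok]
    left <- left[!ok]
  }
  out
}

#' Read a delimited search log
#'
#' Reads a CSV (or TSV) search log into a record table. Malformed rows
#' (unparseable timestamp or empty subject id) are skipped with a warning
#' reporting the count; the number skipped is also attached as the
#' `n_skipped` attribute. Empty query strings are legal.
#'
#' @param path Path to the log file.
#' @param dialect A [log_dialect()].
#' @param sep Field separator (`","` or `"\t"`).
#' @return A data frame with columns `subject_id`, `timestamp`
#'   (`POSIXct`), `engine` and `query`, one row per well-formed record in
#'   file order.
#' @export
read_search_log <- function(path, dialect = log_dialect(), sep = ",") {
  if (!file.exists(path)) stop("search log not found: ", path)
  raw <- utils::read.csv(path, sep = sep, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  need <- c(dialect$subject, dialect$timestamp, dialect$engine, dialect$query)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("search log is missing declared column(s): ",
         paste(missing_cols, collapse = ", "))
  ts <- .parse_ts(raw[[dialect$timestamp]], dialect)
  ok <- !is.na(ts) & nzchar(trimws(raw[[dialect$subject]]))
  n_skipped <- sum(!ok)
  if (n_skipped > 0)
    warning(sprintf("skipped %d malformed row(s) in %s", n_skipped, path))
  out <- data.frame(
    subject_id = trimws(raw[[dialect$subject]][ok]),
    timestamp = ts[ok],
    engine = raw[[dialect$engine]][ok],
    query = raw[[dialect$query]][ok],
    stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a per-subject clinical table
#'
#' Expected columns: `subject_id`, `age`, `sex`, `education`,
#' `evaluation_date`; any remaining numeric columns are treated as raw
#' neuropsychological test scores.
#'
#' @param path Path to a CSV file.
#' @return A data frame; the names of the test-score columns are attached
#'   as attribute `test_cols`.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("clinical table not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "education", "evaluation_date")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("clinical table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  x$evaluation_date <- as.Date(x$evaluation_date)
  if (anyNA(x$evaluation_date)) stop("unparseable evaluation_date in ", path)
  x$sex <- tolower(trimws(x$sex))
  if (!all(x$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'")
  attr(x, "test_cols") <- setdiff(names(x), need)
  x
}

#' The default major-engine set
#'
#' @return Character vector of canonical engine labels.
#' @export
default_engines <- function() c("google", "bing", "yahoo", "ask")

# "https://search.yahoo.com/..." , "Ask.com", "Google" -> canonical label
canonical_engine <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- sub("^[a-z]+://", "", x)
  x <- sub("/.*$", "", x)
  x <- sub("^www\\.", "", x)
  parts <- strsplit(x, ".", fixed = TRUE)
  vapply(parts, function(p) {
    if (!length(p)) return("")
    if (length(p) == 1L) return(p)
    lab <- p[length(p) - 1L]
    if (lab %in% c("co", "com", "org", "net", "ac", "gov") && length(p) >= 3L)
      lab <- p[length(p) - 2L]
    lab
  }, "")
}

#' Restrict records to major search engines
#'
#' Keeps only records whose engine label, after canonicalization
#' (case-folding, stripping scheme/path/`www.` and public-suffix parts),
#' is in the configured engine set. Searches on other websites are a
#' different kind of query and are dropped. Order is preserved.
#'
#' @param records A record table from [read_search_log()].
#' @param engines Canonical engine labels to keep.
#' @return The filtered record table.
#' @examples
#' recs <- data.frame(subject_id = "a", timestamp = Sys.time(),
#'                    engine = c("Google", "target.com", "Ask.com"),
#'                    query = "x")
#' filter_engine(recs)$engine
#' @export
filter_engine <- function(records, engines = default_engines()) {
  records[canonical_engine(records$engine) %in% tolower(engines), ,
          drop = FALSE]
}

#' Window records to a subject's cognitive evaluation
#'
#' Keeps records within `window_days` calendar days (inclusive, time of
#' day ignored) of each subject's evaluation date. Subjects present in
#' the input whose records all fall outside the window are reported in
#' the `excluded_subjects` attribute: their search data cannot be used.
#'
#' @param records A record table (any subset of subjects).
#' @param clinical A clinical table from [read_clinical_table()].
#' @param window_days Half-width of the window in days (default 91,
#'   i.e. 3 months).
#' @return The filtered record table with attribute `excluded_subjects`.
#' @export
window_to_evaluation <- function(records, clinical, window_days = 91) {
  idx <- match(records$subject_id, clinical$subject_id)
  if (anyNA(idx)) {
    miss <- unique(records$subject_id[is.na(idx)])
    stop("subject(s) absent from clinical table: ",
         paste(miss, collapse = ", "))
  }
  eval_date <- as.Date(clinical$evaluation_date)[idx]
  keep <- abs(as.numeric(as.Date(records$timestamp) - eval_date)) <= window_days
  out <- records[keep, , drop = FALSE]
  attr(out, "excluded_subjects") <-
    setdiff(unique(records$subject_id), unique(out$subject_id))
  attr(out, "n_skipped") <- attr(records, "n_skipped")
  out
}
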