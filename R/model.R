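# Covariate-adjusted directional linear models: cognitive z-score on one
# lexical metric plus age, sex and education, with a one-sided test for
# the metric and variance-inflation diagnostics.

#' Fit a covariate-adjusted directional linear model
#'
#' Ordinary least squares of a cognitive outcome on covariates plus one
#' lexical metric of interest, with a one-sided p-value for the metric
#' (the direction of association is hypothesized before fitting) and
#' two-sided p-values for the covariates. Variance inflation factors are
#' computed for every predictor.
#'
#' @param formula Model formula, e.g.
#'   `cognitive_z ~ age + sex + education + unique_terms_per_search`.
#' @param data Data frame containing the variables.
#' @param metric Name of the term receiving the one-sided test; defaults
#'   to the last term of the formula.
#' @param direction Hypothesized sign of the metric coefficient: `+1`
#'   (default) or `-1`.
#' @return An object of class `lexical_lm`: the underlying `lm` fit plus
#'   the coefficient table, `p_one_sided` for the metric, `r_squared`,
#'   `n`, and the VIF map.
#' @seealso [model_vif()], [extreme_contrast()], [lexical_models()]
#' @examples
#' d <- data.frame(age = c(70, 75, 80, 85, 72, 78), sex = rep(0:1, 3),
#'                 education = c(12, 16, 14, 18, 12, 15),
#'                 m = c(1.2, 2.5, 0.8, 3.0, 1.9, 2.2))
#' d$z <- 1 - 0.02 * d$age + 0.4 * d$m + rnorm(6, sd = 0.1)
#' fit <- lexical_lm(z ~ age + sex + education + m, d)
#' summary(fit)
#' @export
lexical_lm <- function(formula, data, metric = NULL, direction = 1) {
  stopifnot(direction %in% c(-1, 1))
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  if (nrow(X) < ncol(X) + 1L)
    stop("need at least ", ncol(X) + 1L, " observations to fit ",
         ncol(X), " parameters")
  fit <- stats::lm(formula, data = data)
  sm <- summary(fit)
  ct <- sm$coefficients
  terms_lab <- attr(stats::terms(formula, data = data), "term.labels")
  if (is.null(metric)) metric <- terms_lab[length(terms_lab)]
  # match the metric term to its design column (factors expand names)
  metric_col <- if (metric %in% rownames(ct)) metric else {
    hits <- rownames(ct)[startsWith(rownames(ct), metric)]
    if (length(hits) != 1L)
      stop("cannot identify a unique coefficient for metric '", metric, "'")
    hits
  }
  est <- ct[metric_col, "Estimate"]
  p2 <- ct[metric_col, "Pr(>|t|)"]
  p1 <- if (sign(est) == direction || est == 0) p2 / 2 else 1 - p2 / 2
  vifs <- if (ncol(X) >= 3L) model_vif(X[, -1L, drop = FALSE]) else {
    # VIF is undefined with a single predictor
    structure(stats::setNames(rep(NA_real_, ncol(X) - 1L),
                              colnames(X)[-1L]),
              flagged = character(0), threshold = 2.5)
  }
  structure(list(
    fit = fit,
    formula = formula,
    metric = metric,
    metric_col = metric_col,
    direction = direction,
    coefficients = ct,
    p_one_sided = p1,
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    sigma = sm$sigma,
    n = nrow(X),
    vif = vifs,
    data = mf
  ), class = "lexical_lm")
}

#' Variance inflation factors
#'
#' For each predictor j, `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is the
#' coefficient of determination of the auxiliary regression of predictor
#' j on all the others (with intercept). Mutually orthogonal centered
#' predictors give VIF 1; a perfectly collinear predictor gives `Inf`.
#' Values at or above 2.5 are flagged (attribute `flagged`), the
#' threshold below which multicollinearity bias can reasonably be
#' ignored for these models.
#'
#' @param x A `lexical_lm` object, or a numeric matrix/data frame of
#'   predictor columns (no intercept column).
#' @param threshold Flagging threshold.
#' @return Named numeric vector of VIFs with attribute `flagged`.
#' @export
model_vif <- function(x, threshold = 2.5) {
  if (inherits(x, "lexical_lm")) return(x$vif)
  X <- as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) < 2L) stop("VIF needs at least 2 predictors")
  out <- vapply(seq_len(ncol(X)), function(j) {
    yj <- X[, j]
    Zj <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Zj, yj)
    sst <- sum((yj - mean(yj))^2)
    if (sst == 0) return(Inf)  # constant column
    r2 <- 1 - sum(fit$residuals^2) / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  names(out) <- colnames(X)
  attr(out, "flagged") <- names(out)[out >= threshold]
  attr(out, "threshold") <- threshold
  out
}

#' Predicted outcome difference between the extremes of a predictor
#'
#' `beta * (x_max - x_min)`: the model-predicted difference in the
#' outcome between the subject with the largest and the subject with the
#' smallest value of the metric, all covariates held fixed.
#'
#' @param object A `lexical_lm` fit or a single coefficient value.
#' @param x_max,x_min The extreme predictor values; for a fit they
#'   default to the observed range of the metric.
#' @return The predicted outcome difference (numeric scalar).
#' @examples
#' extreme_contrast(0.39, x_max = 3.1, x_min = 0.5)
#' @export
extreme_contrast <- function(object, x_max = NULL, x_min = NULL) {
  beta <- if (inherits(object, "lexical_lm"))
    unname(object$coefficients[object$metric_col, "Estimate"])
  else as.numeric(object)
  if (inherits(object, "lexical_lm") && (is.null(x_max) || is.null(x_min))) {
    x <- object$data[[object$metric]]
    if (is.null(x_max)) x_max <- max(x)
    if (is.null(x_min)) x_min <- min(x)
  }
  if (is.null(x_max) || is.null(x_min))
    stop("x_max and x_min are required when a bare coefficient is given")
  if (x_max < x_min) stop("x_max must be >= x_min")
  beta * (x_max - x_min)
}

#' @export
print.lexical_lm <- function(x, digits = 4, ...) {
  cat("Directional lexical model (OLS)\n")
  cat("  ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  n = %d, R-squared = %.3f\n", x$n, x$r_squared))
  cat(sprintf("  metric '%s': beta = %.4g (SE %.4g), one-sided p = %.4g (hypothesized %s)\n",
              x$metric, x$coefficients[x$metric_col, "Estimate"],
              x$coefficients[x$metric_col, "Std. Error"], x$p_one_sided,
              if (x$direction > 0) "positive" else "negative"))
  invisible(x)
}

#' @export
summary.lexical_lm <- function(object, ...) {
  ct <- object$coefficients
  p <- ct[, "Pr(>|t|)"]
  one_sided <- rownames(ct) == object$metric_col
  p[one_sided] <- object$p_one_sided
  tab <- data.frame(
    estimate = ct[, "Estimate"],
    se = ct[, "Std. Error"],
    p_value = p,
    sided = ifelse(one_sided, "one-sided", "two-sided"),
    row.names = rownames(ct)
  )
  out <- list(table = tab, r_squared = object$r_squared,
              adj_r_squared = object$adj_r_squared, n = object$n,
              vif = object$vif, metric = object$metric,
              formula = object$formula)
  class(out) <- "summary.lexical_lm"
  out
}

#' @export
print.summary.lexical_lm <- function(x, digits = 4, ...) {
  cat("Directional lexical model: ", deparse(x$formula), "\n", sep = "")
  tab <- x$table
  tab$estimate <- signif(tab$estimate, digits)
  tab$se <- signif(tab$se, digits)
  tab$p_value <- signif(tab$p_value, digits)
  print(tab)
  cat(sprintf("n = %d, R-squared = %.3f (adj. %.3f)\n",
              x$n, x$r_squared, x$adj_r_squared))
  v <- x$vif
  cat("VIF: ", paste(sprintf("%s %.2f", names(v), v), collapse = ", "),
      "\n", sep = "")
  fl <- attr(v, "flagged")
  if (length(fl))
    cat("WARNING: VIF >= ", attr(v, "threshold"), " for: ",
        paste(fl, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
coef.lexical_lm <- function(object, ...) stats::coef(object$fit)

#' @export
predict.lexical_lm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$fit, ...)
  else stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.lexical_lm <- function(object, ...) stats::residuals(object$fit)

#' @export
fitted.lexical_lm <- function(object, ...) stats::fitted(object$fit)

#' @export
simulate.lexical_lm <- function(object, nsim = 1, seed = NULL, ...)
  stats::simulate(object$fit, nsim = nsim, seed = seed, ...)

#' Scatter plot of outcome against the lexical metric
#'
#' Plots the observed outcome against the metric with the model-implied
#' regression line (evaluated at covariate means) as a dashed line.
#'
#' @param x A `lexical_lm` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lexical_lm <- function(x, ...) {
  d <- x$data
  xv <- d[[x$metric]]
  yv <- stats::model.response(d)
  graphics::plot(xv, yv, xlab = x$metric, ylab = names(d)[1], ...)
  b <- stats::coef(x$fit)
  others <- setdiff(names(b), c("(Intercept)", x$metric_col))
  X <- stats::model.matrix(x$formula, d)
  icpt <- b[["(Intercept)"]] +
    sum(b[others] * colMeans(X[, others, drop = FALSE]))
  graphics::abline(a = icpt, b = b[[x$metric_col]], lty = 2)
  invisible(x)
}

#' Fit the three lexical models
#'
#' Fits one directional model per lexical metric, all with the same
#' outcome and covariates, and returns them as a set with a staircase
#' comparison table (each metric appears only in its own model).
#'
#' @param data Data frame with the outcome, covariates and metrics (for
#'   example, the merge of [subject_profiles()] and [composite_scores()]).
#' @param metrics Character vector of metric column names.
#' @param covariates Character vector of covariate column names.
#' @param outcome Outcome column name.
#' @param directions Hypothesized sign per metric (recycled).
#' @return An object of class `lexical_lm_set` (a named list of
#'   `lexical_lm` fits).
#' @export
lexical_models <- function(data,
                           metrics = c("unique_terms_per_search",
                                       "mean_word_length",
                                       "mean_obscurity"),
                           covariates = c("age", "sex", "education"),
                           outcome = "cognitive_z",
                           directions = 1) {
  directions <- rep_len(directions, length(metrics))
  fits <- lapply(seq_along(metrics), function(i) {
    fml <- stats::reformulate(c(covariates, metrics[i]), response = outcome)
    lexical_lm(fml, data, metric = metrics[i], direction = directions[i])
  })
  names(fits) <- metrics
  structure(fits, class = "lexical_lm_set")
}

#' Model-comparison table for a set of lexical models
#'
#' One row per coefficient (constant, covariates, then each metric), one
#' column per model; a metric's cell is blank in the models that do not
#' include it. Estimates are shown as `estimate (SE)` with the metric
#' rows carrying their one-sided p-values as footnotes.
#'
#' @param set A `lexical_lm_set`.
#' @return A character data frame (the formatted table) with attribute
#'   `p_values`.
#' @export
model_table <- function(set) {
  stopifnot(inherits(set, "lexical_lm_set"))
  all_rows <- unique(unlist(lapply(set, function(f) rownames(f$coefficients))))
  fmt <- function(est, se) sprintf("%.3f (%.3f)", est, se)
  cols <- lapply(set, function(f) {
    ct <- f$coefficients
    out <- setNames(rep("", length(all_rows)), all_rows)
    out[rownames(ct)] <- fmt(ct[, "Estimate"], ct[, "Std. Error"])
    out
  })
  tab <- data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  names(tab) <- paste0("Model ", seq_along(set), " (", names(set), ")")
  pvals <- vapply(set, function(f) f$p_one_sided, 0)
  r2 <- vapply(set, function(f) f$r_squared, 0)
  attr(tab, "p_values") <- pvals
  attr(tab, "r_squared") <- r2
  tab
}

#' @export
print.lexical_lm_set <- function(x, ...) {
  tab <- model_table(x)
  cat("Three-model comparison (one-sided p for each lexical metric;\n")
  cat("no multiple-testing correction is applied across models)\n\n")
  print(tab)
  cat("\nR-squared: ",
      paste(sprintf("%.3f", attr(tab, "r_squared")), collapse = ", "),
      "\nOne-sided p (metric): ",
      paste(sprintf("%.4g", attr(tab, "p_values")), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
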