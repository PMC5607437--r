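test_that("noiseless outcomes are recovered exactly", {
  set.seed(2)
  d <- data.frame(age = runif(20, 65, 95), female = rbinom(20, 1, 0.8),
                  education = sample(10:20, 20, TRUE),
                  m = runif(20, 0.5, 3))
  d$z <- 0.75 - 0.024 * d$age + 0.27 * d$female + 0.016 * d$education +
    0.39 * d$m
  fit <- lexical_lm(z ~ age + female + education + m, d, metric = "m")
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(unname(coef(fit)),
               c(0.75, -0.024, 0.27, 0.016, 0.39), tolerance = 1e-8)
})

test_that("OLS matches the normal-equation oracle on random small designs", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(8:20, 1)
    p <- sample(2:4, 1)
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("x", seq_len(p))
    y <- rnorm(n)
    d <- data.frame(y = y, X)
    fml <- stats::reformulate(colnames(X), "y")
    fit <- lexical_lm(fml, d)
    want <- oracle_ols(cbind(1, X), y)
    expect_equal(unname(coef(fit)), unname(want), tolerance = 1e-8)
  }
})

test_that("the one-sided p-value halves when the sign is as hypothesized", {
  set.seed(4)
  d <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
  d$y <- 0.3 * d$x1 - 0.3 * d$x2 + rnorm(40)
  up <- lexical_lm(y ~ x1 + x2, d, metric = "x1", direction = 1)
  p2 <- up$coefficients["x1", "Pr(>|t|)"]
  expect_equal(up$p_one_sided, p2 / 2)
  # estimate against the hypothesized direction: complement rule
  down <- lexical_lm(y ~ x1 + x2, d, metric = "x2", direction = 1)
  p2n <- down$coefficients["x2", "Pr(>|t|)"]
  expect_equal(down$p_one_sided, 1 - p2n / 2)
  expect_true(up$p_one_sided > 0 && up$p_one_sided < 1)
  expect_true(down$p_one_sided > 0 && down$p_one_sided < 1)
})

test_that("R-squared is non-decreasing under predictor addition", {
  set.seed(5)
  d <- data.frame(a = rnorm(30), b = rnorm(30), m = rnorm(30))
  d$y <- 0.5 * d$a + rnorm(30)
  base <- lexical_lm(y ~ a + b, d, metric = "b")
  full <- lexical_lm(y ~ a + b + m, d, metric = "m")
  expect_gte(full$r_squared, base$r_squared)
})

test_that("VIF diagnostics behave at the boundaries and match car", {
  # exactly orthogonal centered predictors -> VIF 1
  X <- cbind(x1 = c(1, 1, -1, -1), x2 = c(1, -1, 1, -1),
             x3 = c(1, -1, -1, 1))
  v <- model_vif(X)
  expect_equal(as.numeric(v), rep(1, 3))
  expect_length(attr(v, "flagged"), 0)
  # duplicated column -> infinite VIF
  X2 <- cbind(a = rnorm(10), b = rnorm(10))
  X2 <- cbind(X2, c = X2[, "a"])
  v2 <- model_vif(X2)
  expect_true(is.infinite(v2[["a"]]) && is.infinite(v2[["c"]]))
  expect_true(all(c("a", "c") %in% attr(v2, "flagged")))
  # rank-deficient design is refused with the collinear column named
  d <- data.frame(y = rnorm(10), a = rnorm(10))
  d$b <- 2 * d$a
  expect_error(lexical_lm(y ~ a + b, d), "collinear.*b")
  # cross-check against car::vif on a well-behaved design
  skip_if_not_installed("car")
  set.seed(6)
  dd <- data.frame(y = rnorm(50), u = rnorm(50), v = rnorm(50))
  dd$w <- 0.6 * dd$u + rnorm(50)
  ours <- model_vif(as.matrix(dd[c("u", "v", "w")]))
  theirs <- car::vif(stats::lm(y ~ u + v + w, dd))
  expect_equal(as.numeric(ours), unname(theirs[c("u", "v", "w")]),
               tolerance = 1e-10)
})

test_that("extreme-contrast predictions follow beta times the range", {
  expect_equal(extreme_contrast(0.39, 3.1, 0.5), 1.014)
  expect_equal(extreme_contrast(1.39, 0.52, 0.044), 0.66164)
  expect_equal(extreme_contrast(0, 10, 0), 0)
  expect_error(extreme_contrast(1, x_max = 1, x_min = 2), "x_max")
  # from a fitted model, defaults to the observed metric range
  d <- data.frame(x = c(0.5, 1, 2, 3.1), y = c(1, 2, 3, 4),
                  a = c(0, 1, 0, 1), b = c(2, 1, 2, 1))
  fit <- lexical_lm(y ~ x, d, metric = "x")
  expect_equal(extreme_contrast(fit),
               unname(coef(fit)["x"]) * (3.1 - 0.5))
})

test_that("the three-model set lays out a staircase table", {
  st <- generate_cohort(generator_config(seed = 9))
  d <- st$subjects
  names(d)[names(d) == "unique_terms"] <- "unique_terms_per_search"
  names(d)[names(d) == "word_length"] <- "mean_word_length"
  names(d)[names(d) == "obscurity"] <- "mean_obscurity"
  set <- lexical_models(d, covariates = c("age", "female", "education"))
  expect_s3_class(set, "lexical_lm_set")
  tab <- model_table(set)
  expect_equal(ncol(tab), 3)
  expect_equal(nrow(tab), 7)  # intercept + 3 covariates + 3 metrics
  # each metric's cell is blank outside its own model
  expect_equal(tab["mean_obscurity", 1], "")
  expect_equal(tab["unique_terms_per_search", 3], "")
  expect_true(nzchar(tab["unique_terms_per_search", 1]))
  expect_output(print(set), "Three-model comparison")
})

test_that("prediction, residuals and simulation delegate to the fit", {
  set.seed(8)
  d <- data.frame(x = rnorm(15), w = rnorm(15))
  d$y <- 1 + d$x + rnorm(15)
  fit <- lexical_lm(y ~ x + w, d, metric = "x")
  expect_equal(unname(fitted(fit) + residuals(fit)), d$y)
  nd <- data.frame(x = 0, w = 0)
  expect_equal(unname(predict(fit, nd)), unname(coef(fit)[1]))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(15L, 3L))
  # insufficient observations are refused
  expect_error(lexical_lm(y ~ x + w, d[1:3, ]), "at least")
})
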