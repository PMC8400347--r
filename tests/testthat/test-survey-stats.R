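test_that("under SRS collapse the fit reproduces textbook weighted least squares", {
  set.seed(101)
  n <- 120
  d <- data.frame(y = rnorm(n, 50, 10), x = runif(n), g = gl(3, n / 3),
                  weight = 1, stratum_id = 1L, psu_id = seq_len(n))
  fit <- fit_survey_wls(y ~ x + g, d)
  ols <- lm(y ~ x + g, d)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(fit$df, n - 1)

  # SEs match the robust (sandwich-type) oracle with the n/(n-1) factor
  X <- model.matrix(ols)
  V <- oracle_linearization(X, d$y, rep(1, n), d$stratum_id, d$psu_id)
  expect_equal(unname(sqrt(diag(vcov(fit)))), unname(sqrt(diag(V))),
               tolerance = 1e-10)

  # with non-uniform weights the point estimates still equal textbook WLS
  d$weight <- runif(n, 0.5, 3)
  fitw <- fit_survey_wls(y ~ x + g, d)
  wls <- lm(y ~ x + g, d, weights = weight)
  expect_equal(unname(coef(fitw)), unname(coef(wls)), tolerance = 1e-10)
})

test_that("two-strata covariance matches the brute-force linearization oracle", {
  set.seed(202)
  n <- 160
  d <- data.frame(y = rnorm(n, 100, 20), x = rnorm(n),
                  weight = runif(n, 0.5, 4),
                  stratum_id = rep(1:2, each = n / 2),
                  psu_id = rep(rep(1:4, each = n / 8), 2))
  fit <- fit_survey_wls(y ~ x, d)
  X <- cbind(1, d$x)
  V <- oracle_linearization(X, d$y, d$weight, d$stratum_id, d$psu_id)
  expect_equal(unname(fit$vcov), unname(V), tolerance = 1e-10)
  expect_equal(fit$df, 8 - 2)
})

test_that("degenerate outcomes, weight scaling, and design errors behave", {
  set.seed(303)
  d <- data.frame(y = 7, x = rnorm(40), weight = runif(40, 1, 2),
                  stratum_id = rep(1:2, 20), psu_id = rep(1:4, 10))
  fit <- fit_survey_wls(y ~ x, d)
  expect_equal(unname(coef(fit)), c(7, 0))
  expect_equal(max(abs(vcov(fit))), 0)

  # multiplying all weights by a constant changes nothing
  d$y <- rnorm(40, 10, 2)
  f1 <- fit_survey_wls(y ~ x, d)
  d2 <- transform(d, weight = weight * 1000)
  f2 <- fit_survey_wls(y ~ x, d2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  expect_equal(vcov(f1), vcov(f2), tolerance = 1e-9)

  # aliased columns are named
  d$z <- d$x
  expect_error(fit_survey_wls(y ~ x + z, d), "aliased.*z")

  # lonely PSU: centered at the grand mean by default, error on request
  dl <- data.frame(y = rnorm(30), x = rnorm(30), weight = 1,
                   stratum_id = c(rep(1, 29), 2),
                   psu_id = c(rep(1:4, length.out = 29), 1))
  fl <- fit_survey_wls(y ~ x, dl)
  expect_equal(fl$lonely_strata, "2")
  expect_error(fit_survey_wls(y ~ x, dl, lonely = "fail"), "single PSU")
})

test_that("the transform ladder picks the first rung with acceptable skewness", {
  set.seed(404)
  n <- 400
  d <- data.frame(g = gl(2, n / 2), weight = 1, stratum_id = 1L,
                  psu_id = seq_len(n))
  d$y <- rnorm(n, 100, 10)
  expect_equal(normalize_residuals(y ~ g, d)$transform, "identity")

  d$y <- exp(rnorm(n, 3, 1))  # log-normal outcome
  nr <- normalize_residuals(y ~ g, d)
  expect_equal(nr$transform, "log")
  expect_true(nr$accepted)

  d$y <- 5
  nr0 <- normalize_residuals(y ~ g, d)
  expect_equal(nr0$transform, "identity")
  expect_equal(unname(nr0$skewness["identity"]), 0)

  # non-positive outcomes make log/negative rungs inapplicable
  d$y <- c(-abs(rnorm(n / 2, 5)), abs(rnorm(n / 2, 5)))^3
  nr2 <- normalize_residuals(y ~ g, d)
  expect_false(nr2$transform %in% c("log", "inv_sqrt", "inverse", "sqrt"))
})

test_that("least-squares means reduce to weighted group means without covariates", {
  set.seed(505)
  n <- 90
  d <- data.frame(g = gl(3, n / 3), weight = runif(n, 0.5, 2),
                  stratum_id = 1L, psu_id = seq_len(n))
  d$y <- rnorm(n, 100, 15)
  fit <- fit_survey_wls(y ~ g, d)
  ls <- lsm(fit, "g")
  wm <- vapply(levels(d$g), function(l) {
    with(d[d$g == l, ], sum(weight * y) / sum(weight))
  }, numeric(1))
  expect_equal(ls$lsm, unname(wm), tolerance = 1e-10)

  # identical groups: every pairwise difference is zero
  d$y <- rep(rnorm(n / 3, 100, 15), 3)
  d$weight <- rep(runif(n / 3, 0.5, 2), 3)
  fit2 <- fit_survey_wls(y ~ g, d)
  pw <- tukey_pairwise(lsm(fit2, "g"))
  expect_equal(pw$pairs$estimate, rep(0, 3), tolerance = 1e-10)
})

test_that("a planted group effect is recovered with covariate adjustment", {
  set.seed(606)
  n <- 600
  d <- data.frame(g = factor(sample(c("a", "b"), n, TRUE)),
                  age = runif(n, 2, 17), weight = runif(n, 0.5, 2),
                  stratum_id = rep(1:5, length.out = n),
                  psu_id = rep(1:2, length.out = n))
  delta <- 200
  d$y <- 1500 + delta * (d$g == "b") + 20 * d$age + rnorm(n, 0, 150)
  fit <- fit_survey_wls(y ~ g + age, d)
  pw <- tukey_pairwise(lsm(fit, "g"))
  est <- -pw$pairs$estimate[1]  # b - a
  expect_lt(abs(est - delta), 4 * pw$pairs$se[1])
})

test_that("Tukey adjustment matches the k=2 closed form and orders p-values", {
  set.seed(707)
  n <- 80
  d <- data.frame(g = gl(2, n / 2), weight = 1, stratum_id = 1L,
                  psu_id = seq_len(n))
  d$y <- rnorm(n, 10, 2)
  pw <- tukey_pairwise(lsm(fit_survey_wls(y ~ g, d), "g"))
  # for two groups the studentized-range p equals the two-sided t-test p
  expect_equal(pw$pairs$p_adjusted, pw$pairs$p_unadjusted, tolerance = 1e-9)

  d4 <- data.frame(g = gl(4, 25), weight = 1, stratum_id = 1L, psu_id = 1:100)
  d4$y <- rnorm(100, 10, 2)
  pw4 <- tukey_pairwise(lsm(fit_survey_wls(y ~ g, d4), "g"))
  expect_true(all(pw4$pairs$p_adjusted >= pw4$pairs$p_unadjusted - 1e-12))
  expect_error(tukey_pairwise(lsm(fit_survey_wls(y ~ g, d4), "g")[1, ]),
               "at least 2")

  # one group far from three equal ones: letters a/a/a/b
  d4$y <- rnorm(100, 10, 1) + ifelse(d4$g == "4", 50, 0)
  pw_far <- tukey_pairwise(lsm(fit_survey_wls(y ~ g, d4), "g"))
  expect_equal(unname(pw_far$letters), c("a", "a", "a", "b"))
})
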