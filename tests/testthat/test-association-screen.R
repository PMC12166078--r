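make_screen_data <- function(n = 2000, seed = 1, effect = 0) {
  set.seed(seed)
  d <- data.frame(sex = rbinom(n, 1, 0.5), age = rnorm(n, 10, 0.5))
  for (k in 1:3) d[[paste0("PC", k)]] <- rnorm(n)
  d$x <- rnorm(n)
  d$y <- 0.2 * d$sex + 0.1 * d$age + sqrt(effect) * d$x +
    sqrt(1 - effect) * rnorm(n)
  d
}

test_that("incremental R-squared has the right limits and null behaviour", {
  d <- make_screen_data(500, 3)
  d$y2 <- d$x + rnorm(500, 0, 1e-6)
  r <- incremental_r2(d, "y2", "x")
  expect_equal(r$incremental_r2, 1, tolerance = 1e-8)

  # independent predictor: tiny increment, non-extreme p
  r0 <- incremental_r2(d, "y", "x", covariates = c("sex", "age", "PC1"))
  expect_lt(r0$incremental_r2, 0.02)
  expect_true(r0$p > 0 && r0$p <= 1)

  # simulated 6% effect beyond covariates
  d6 <- make_screen_data(5000, 5, effect = 0.06)
  r6 <- incremental_r2(d6, "y", "x", covariates = c("sex", "age"))
  expect_lt(abs(r6$incremental_r2 - 0.06), 0.015)

  d$const <- 1
  expect_error(incremental_r2(d, "y", "const"), "constant")
})

test_that("incremental R-squared is invariant to covariate reparameterisation", {
  d <- make_screen_data(1000, 7, effect = 0.03)
  r1 <- incremental_r2(d, "y", "x", covariates = c("PC1", "PC2", "PC3"))
  # invertible linear recombination of the covariate block
  d$Q1 <- d$PC1 + d$PC2
  d$Q2 <- d$PC1 - d$PC2
  d$Q3 <- 2 * d$PC3 + 0.5 * d$PC1
  r2 <- incremental_r2(d, "y", "x", covariates = c("Q1", "Q2", "Q3"))
  expect_equal(r1$incremental_r2, r2$incremental_r2, tolerance = 1e-10)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-8)
})

test_that("null ANOVA-F p-values are uniform", {
  ps <- vapply(1:300, function(s) {
    d <- make_screen_data(300, 10000 + s)
    incremental_r2(d, "y", "x", covariates = c("sex", "age"))$p
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("proportional-odds fits match closed forms and special cases", {
  set.seed(11)
  n <- 4000
  y <- sample(1:3, n, replace = TRUE, prob = c(0.2, 0.3, 0.5))
  d <- data.frame(y = y)
  f0 <- fit_proportional_odds(d, "y")
  cum <- cumsum(table(y) / n)
  expect_equal(unname(f0$zeta), qlogis(cum[1:2]), tolerance = 1e-4,
               ignore_attr = TRUE)

  # latent-threshold slope recovery
  x <- rnorm(n)
  lat <- 0.5 * x + rlogis(n)
  yy <- cut(lat, c(-Inf, 0, 1.2, Inf), labels = FALSE)
  d2 <- data.frame(y = yy, x = x)
  f1 <- fit_proportional_odds(d2, "y", "x")
  est <- f1$coefficients$estimate[1]
  se <- f1$coefficients$se[1]
  expect_lt(abs(est - 0.5) / se, 3)

  # two observed levels: matches ordinary logistic regression
  d3 <- data.frame(y = ifelse(yy == 3, 2, 1), x = x)
  f2 <- fit_proportional_odds(d3, "y", "x")
  glmfit <- glm(I(y == 2) ~ x, data = d3, family = binomial)
  expect_equal(f2$coefficients$estimate[1], unname(coef(glmfit)["x"]),
               tolerance = 1e-4)
  expect_error(fit_proportional_odds(data.frame(y = rep(1, 10)), "y"),
               "2 observed levels")
})

test_that("incremental Nagelkerke R-squared behaves at the null and identity", {
  set.seed(21)
  n <- 3000
  pgs <- rnorm(n)
  y <- ordinalize(rnorm(n), c(0.2, 0.3, 0.5))
  d <- data.frame(y = as.integer(y), pgs = pgs, sex = rbinom(n, 1, 0.5))
  r <- incremental_nagelkerke(d, "y", "pgs", "sex")
  expect_lt(abs(r$incremental_r2), 0.005)
  expect_gte(r$incremental_r2 + 1e-9, 0)
  expect_true(r$p > 0 && r$p <= 1)
})

test_that("Bonferroni thresholds reproduce the published constants", {
  expect_equal(bonferroni(154), 0.000324, tolerance = 1e-5 / 0.000324)
  expect_equal(bonferroni(154), 0.05 / 154, tolerance = 1e-15)
  expect_identical(bonferroni(20), 0.0025)
  expect_identical(bonferroni(1), 0.05)
  expect_error(bonferroni(0), ">= 1")
})

test_that("spectral decomposition effective test counts match hand calculations", {
  M <- 7
  id <- meff_spectral(diag(M))
  expect_equal(id$raw, M, tolerance = 1e-10)
  expect_equal(meff_spectral(diag(M), "nyholt")$raw, M, tolerance = 1e-10)

  ones <- meff_spectral(matrix(1, 25, 25))
  expect_equal(ones$raw, 1, tolerance = 1e-8)

  R2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_equal(meff_spectral(R2, "li_ji")$raw, 2.0, tolerance = 1e-10)
  expect_equal(meff_spectral(R2, "nyholt")$raw, 1.75, tolerance = 1e-10)

  expect_error(meff_spectral(matrix(c(1, 0.2, 0.4, 1), 2, 2)), "symmetric")

  # 1 <= Meff <= M on random PSD correlation matrices
  set.seed(33)
  for (i in 1:20) {
    p <- sample(3:10, 1)
    A <- matrix(rnorm(p * p), p)
    R <- cov2cor(crossprod(A) + diag(p))
    for (meth in c("li_ji", "nyholt")) {
      raw <- meff_spectral(R, meth)$raw
      expect_gte(raw, 1)
      expect_lte(raw, p + 1e-8)
    }
  }
})

test_that("predictor filtering applies the 1% rule inclusively", {
  sc <- data.frame(predictor = rep(c("nursery", "hum", "edge"), each = 2),
                   outcome = rep(c("o1", "o2"), 3),
                   incremental_r2 = c(0.002, 0.006, 0.03, 0.05, 0.01, 0.002))
  kept <- filter_predictors(sc)
  expect_setequal(kept, c("hum", "edge"))
  expect_false("nursery" %in% kept)
  expect_error(filter_predictors(sc[0, ]), "empty")
  expect_warning(filter_predictors(data.frame(predictor = "a", outcome = "b",
                                              incremental_r2 = 0.001)),
                 "retention floor")
})

test_that("analytic PGS power follows the noncentral chi-square", {
  expect_equal(pgs_power(1000, 1e-9), 0.05, tolerance = 1e-4)
  # NCP 7.849 gives 80% power at alpha 0.05
  r2 <- 7.849 / (5000 + 7.849)
  expect_equal(pgs_power(5000, r2), 0.80, tolerance = 1e-4)
  expect_gt(pgs_power(1e6, 0.01), 0.9999)
  expect_error(pgs_power(100, 0), "r2")
  expect_error(pgs_power(100, 0.1, 1.5), "alpha")
})
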