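test_that("implied covariance matches hand algebra", {
  # single factor, lambda = (1,1), psi = 1, theta = I -> [[2,1],[1,2]]
  spec <- fm_spec(c("y1", "y2"), "f")
  spec <- set_path(spec, "f", "y1", free = FALSE, value = 1)
  spec <- set_path(spec, "f", "y2", free = FALSE, value = 1)
  spec <- set_cov(spec, "f", free = FALSE, value = 1)
  spec <- set_cov(spec, "y1", free = FALSE, value = 1)
  spec <- set_cov(spec, "y2", free = FALSE, value = 1)
  expect_equal(unname(implied_covariance(spec, numeric(0))),
               matrix(c(2, 1, 1, 2), 2, 2))

  # reference three-factor model: path tracing hum -> musicality -> speech
  # -> syntax gives 0.74 * 0.42 * 0.59
  m <- stage3_model()
  expect_equal(m$sigma["hum_5y", "syntax_10y"], 0.74 * 0.42 * 0.59,
               tolerance = 1e-12)

  # zero loadings -> diagonal residual matrix
  spec0 <- cfa_spec(matrix(0.5, 2, 1, dimnames = list(c("a", "b"), "f")))
  p0 <- c("f=~a" = 0, "f=~b" = 0, "a~~a" = 1, "b~~b" = 2)
  expect_equal(unname(implied_covariance(spec0, p0)), diag(c(1, 2)))
})

test_that("parameter vector mismatches are rejected", {
  tf <- two_factor_spec()
  expect_error(implied_covariance(tf$spec, tf$params[-1]),
               "does not cover")
})

test_that("saturated model attains F_ML = 0 and T = 0", {
  spec <- fm_spec(c("y1", "y2"))
  spec <- set_cov(spec, "y1")
  spec <- set_cov(spec, "y2")
  spec <- set_cov(spec, "y1", "y2", value = 0.1)
  S <- matrix(c(2, 0.6, 0.6, 1.5), 2, 2, dimnames = list(c("y1", "y2"), c("y1", "y2")))
  fit <- fit_ml(spec, S, n = 100)
  expect_lt(fit$F_ml, 1e-8)
  expect_lt(fit$T, 1e-5)
  expect_equal(fit$df, 0)
  expect_identical(fit$indices[["CFI"]], 1)
  expect_true(is.na(fit$indices[["RMSEA"]]))
})

test_that("two-factor parameter recovery at n = 10000", {
  tf <- two_factor_spec()
  X <- simulate_mvn(10000, tf$sigma, seed = 31)
  fit <- fit_ml(tf$spec, cov(X), nrow(X))
  expect_true(fit$converged)
  expect_true(fit$admissible)
  est <- fit$est[names(tf$params)]
  expect_lt(max(abs(est - tf$params)), 0.03)
  expect_gte(fit$F_ml, 0)
})

test_that("over-parameterised and non-anchored specs are caught before fitting", {
  spec <- fm_spec(c("y1", "y2"), "f")
  spec <- set_path(spec, "f", "y1")
  spec <- set_path(spec, "f", "y2")
  spec <- set_cov(spec, "f", free = FALSE, value = 1)
  spec <- set_cov(spec, "y1")
  spec <- set_cov(spec, "y2")
  S <- matrix(c(1, 0.3, 0.3, 1), 2, 2, dimnames = list(c("y1", "y2"), c("y1", "y2")))
  expect_error(fit_ml(spec, S, 100), "not identified")

  spec2 <- fm_spec("y1", "f")
  spec2 <- set_path(spec2, "f", "y1")
  spec2 <- set_cov(spec2, "f")            # free latent variance, no anchor
  expect_error(fit_ml(spec2, matrix(1, 1, 1, dimnames = list("y1", "y1")), 100),
               "anchor")
})

test_that("non-positive-definite sample covariance names the eigenvalue", {
  tf <- two_factor_spec()
  S <- matrix(1, 4, 4, dimnames = dimnames(tf$sigma))   # rank 1
  expect_error(fit_ml(tf$spec, S, 100), "eigenvalue")
})

test_that("standardisation rescales by implied standard deviations", {
  # lambda = 2, factor variance 1, residual 1 -> standardised 2/sqrt(5)
  L <- matrix(c(2, 1, 1), 3, 1, dimnames = list(paste0("y", 1:3), "f"))
  spec <- cfa_spec(L)
  params <- c("f=~y1" = 2, "f=~y2" = 1, "f=~y3" = 1,
              "y1~~y1" = 1, "y2~~y2" = 1, "y3~~y3" = 1)
  sigma <- implied_covariance(spec, params)
  fit <- fit_ml(spec, sigma, n = 5000)
  std <- standardize(fit)
  expect_equal(std$est_std[std$parameter == "f=~y1"], 2 / sqrt(5),
               tolerance = 1e-4)
  # standardised factor correlations bounded
  tf <- two_factor_spec()
  fitc <- fit_ml(tf$spec, tf$sigma, 2000)
  stdc <- standardize(fitc)
  rho <- stdc$est_std[stdc$parameter == "f1~~f2"]
  expect_true(abs(rho) <= 1)
})

test_that("standardised solution is invariant to observed-variable rescaling", {
  tf <- two_factor_spec()
  X <- simulate_mvn(3000, tf$sigma, seed = 8)
  S <- cov(X)
  D <- diag(c(3, 0.5, 2, 10))
  S2 <- D %*% S %*% D
  dimnames(S2) <- dimnames(S)
  f1 <- fit_ml(tf$spec, S, 3000)
  f2 <- fit_ml(tf$spec, S2, 3000)
  s1 <- standardize(f1); s2 <- standardize(f2)
  m <- match(s1$parameter, s2$parameter)
  expect_equal(s1$est_std, s2$est_std[m], tolerance = 1e-4)
})

test_that("defined parameters equal the product of their components exactly", {
  tr <- stage3_mediation_truth()
  X <- simulate_mvn(2000, tr$sigma, seed = 4)
  fit <- fit_ml(tr$spec, cov(X), 2000)
  std <- standardize(fit)
  g <- function(p) std$est_std[std$parameter == p]
  expect_identical(g("shared_speech"), g("a") * g("b_speech"))
  expect_identical(g("total_speech"), g("a") * g("b_speech") + g("c_speech"))
})

test_that("bootstrap SEs are reproducible and close to analytic ML SEs", {
  L <- matrix(c(0.8, 0.7, 0.6), 3, 1, dimnames = list(paste0("y", 1:3), "f"))
  spec <- cfa_spec(L)
  params <- c("f=~y1" = 0.8, "f=~y2" = 0.7, "f=~y3" = 0.6,
              "y1~~y1" = 0.36, "y2~~y2" = 0.51, "y3~~y3" = 0.64)
  sigma <- implied_covariance(spec, params)
  X <- simulate_mvn(1500, sigma, seed = 12)
  b1 <- bootstrap_se(X, spec, B = 120, seed = 99)
  b2 <- bootstrap_se(X, spec, B = 120, seed = 99)
  expect_identical(b1$se, b2$se)
  expect_equal(b1$n_failed, 0)
  fit <- fit_ml(spec, cov(X), nrow(X))
  std <- standardize(fit)
  lo <- grepl("=~", std$parameter)
  m <- match(std$parameter[lo], names(b1$se))
  expect_lt(max(abs(b1$se[m] / std$se_std[lo] - 1)), 0.25)
})

test_that("bootstrap rejects degenerate cohorts", {
  tf <- two_factor_spec()
  X <- simulate_mvn(2, tf$sigma)
  expect_error(bootstrap_se(X, tf$spec, B = 10), "too few")
})
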