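test_that("Kaiser factor counts follow the eigenvalue spectrum", {
  expect_warning(k0 <- estimate_n_factors(diag(10)), "flat scree")
  expect_equal(as.integer(k0), 0L)

  # two blocks of five with within-block r = 0.8: top eigenvalue 4.2 twice
  R <- diag(10)
  R[1:5, 1:5] <- 0.8; R[6:10, 6:10] <- 0.8; diag(R) <- 1
  k2 <- estimate_n_factors(R)
  expect_equal(as.integer(k2), 2L)
  expect_equal(sort(attr(k2, "eigenvalues"), decreasing = TRUE)[1:2],
               c(4.2, 4.2), tolerance = 1e-8)

  # rank-1 perfect correlation
  expect_equal(as.integer(estimate_n_factors(matrix(1, 3, 3))), 1L)

  expect_error(estimate_n_factors(matrix(c(1, 2, 2, 1), 2, 2)),
               "positive semi-definite")
})

test_that("matched split halves are disjoint, exhaustive and balanced", {
  cfg <- stage3_sim_config(6101, seed = 13)
  co <- generate_cohort(cfg)
  co <- apply_missingness(co, c(syntax_10y = 0.2, verbiq_9y = 0.1), seed = 3)
  h <- split_half(co, seed = 17)
  expect_equal(nrow(h$a) + nrow(h$b), 6101)
  expect_length(intersect(h$a$individual_id, h$b$individual_id), 0)
  # alternation bounds the imbalance by the number of strata
  sig <- apply(is.na(co[, cohort_meta(co)$measure]), 1, paste, collapse = "")
  n_strata <- length(unique(paste(co$sex, sig)))
  expect_lte(abs(nrow(h$a) - nrow(h$b)), n_strata)
  expect_lt(abs(mean(h$a$sex) - mean(h$b$sex)), 0.02)
  # reproducible
  h2 <- split_half(co, seed = 17)
  expect_identical(h$a$individual_id, h2$a$individual_id)
  # degenerate single-sex cohort still splits
  co$sex <- 0L
  h3 <- split_half(co, seed = 1)
  expect_equal(nrow(h3$a) + nrow(h3$b), 6101)
  expect_error(split_half(co, sex_col = "gender"), "stratifier")
})

test_that("two-block EFA recovers simple structure and valid rotations", {
  m <- stage3_model()
  X <- simulate_mvn(4000, m$sigma, seed = 23)
  preds <- rownames(m$loadings)[1:3]
  outs <- rownames(m$loadings)[4:9]
  efa <- efa_two_block(X, preds, outs, 1, 2, rotation = "varimax")
  # predictor block: single factor recovers generating loadings up to sign
  lp <- efa$loadings$predictor
  s <- sign(lp["hum_5y", 1])
  expect_equal(unname(s * lp[, 1]), unname(m$loadings[preds, "musicality"]),
               tolerance = 0.07)
  # outcome block: each generating loading > 0.3 appears on one factor
  lo <- abs(efa$loadings$outcome)
  expect_true(all(apply(lo[c("nonword_9y", "verbiq_9y"), ], 1, max) > 0.4))
  expect_true(all(apply(lo[c("syntax_10y", "intelligibility_10y"), ], 1, max) > 0.4))
  # oblimin returns a proper factor correlation matrix
  efa_o <- efa_two_block(X, preds, outs, 1, 2, rotation = "oblimin")
  Phi <- efa_o$Phi$outcome
  expect_equal(diag(Phi), c(1, 1), tolerance = 1e-8)
  expect_true(abs(Phi[1, 2]) <= 1)
  expect_error(efa_two_block(X, preds, outs, 3, 2), "identification limit")
})

test_that("varimax leaves an orthogonal simple structure unchanged up to sign/permutation", {
  L <- matrix(c(0.8, 0.7, 0, 0,
                0, 0, 0.75, 0.6), 4, 2)
  r <- stats::varimax(L, normalize = FALSE)
  Lr <- matrix(r$loadings, 4, 2)
  recovered <- apply(abs(Lr), 2, max)
  expect_equal(sort(round(abs(Lr)[abs(Lr) > 0.1], 2)),
               sort(c(0.8, 0.7, 0.75, 0.6)), tolerance = 0.02)
})

test_that("loading retention uses a strict threshold", {
  L <- matrix(c(0.05, 0.74), 2, 1, dimnames = list(c("a", "b"), "F1"))
  expect_warning(spec <- build_cfa_spec(L), "dropped")
  expect_identical(spec$observed, "b")

  # exactly 0.1 is NOT retained
  L2 <- matrix(c(0.1, 0.74), 2, 1, dimnames = list(c("a", "b"), "F1"))
  expect_warning(spec2 <- build_cfa_spec(L2), "dropped: a")

  L3 <- matrix(c(0.05, 0.08), 2, 1, dimnames = list(c("a", "b"), "F1"))
  expect_error(suppressWarnings(build_cfa_spec(L3)), "empty model")
})

test_that("confirmation selects by fit and flags meaningful estimates strictly", {
  m <- stage3_model()
  cfg <- stage3_sim_config(4000, seed = 41, ordinal = FALSE)
  co <- generate_cohort(cfg)
  disc <- discover_structure(co, seed = 42)
  expect_equal(disc$n_factors$total, 3L)
  interp <- disc$confirmation$interpretation
  # initiation loading generates at 0.20: retained but not flagged meaningful
  init <- interp[grepl("initiation", interp$parameter) &
                   grepl("=~", interp$parameter), ]
  expect_true(nrow(init) >= 1)
  expect_false(any(init$meaningful))
  # strong loadings flagged
  hum <- interp[grepl("=~hum_5y", interp$parameter), ]
  expect_true(all(hum$meaningful))
  # holdout and full-sample estimates agree within 2 SE
  hold <- standardize(disc$confirmation$holdout_fit)
  full <- standardize(disc$confirmation$full_fit)
  m2 <- match(hold$parameter, full$parameter)
  dev <- abs(hold$est_std - full$est_std[m2]) /
    pmax(sqrt(hold$se_std^2 + full$se_std[m2]^2), 1e-6)
  expect_lt(stats::quantile(dev, 0.9), 2)
})
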