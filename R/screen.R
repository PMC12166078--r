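#' Incremental variance explained by a predictor beyond covariates
#'
#' Fits a reduced linear model (covariates and any extra adjusters only)
#' and a full model adding the predictor on the complete cases shared by
#' both, and returns `R2_full - R2_reduced` with the nested-model ANOVA
#' F-test. Ordinal predictors enter as integer-coded linear terms.
#' Confounder-score adjustment (e.g. an educational-attainment PGS) is done
#' by passing the score in `extra_adjusters`, which places it in *both*
#' models.
#'
#' @param data data frame.
#' @param outcome name of a continuous outcome column.
#' @param predictor name of the predictor column.
#' @param covariates character vector of covariate columns.
#' @param extra_adjusters further columns adjusted for in both models.
#' @return One-row data frame: `predictor`, `outcome`, `n`, `incremental_r2`,
#'   `statistic` (F), `df1`, `df2`, `p`, `adjusted_pgs` flag.
#' @export
incremental_r2 <- function(data, outcome, predictor, covariates = character(),
                           extra_adjusters = character()) {
  cols <- c(outcome, predictor, covariates, extra_adjusters)
  missing <- setdiff(cols, names(data))
  if (length(missing)) stop("columns absent: ", paste(missing, collapse = ", "))
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols, drop = FALSE]
  n <- nrow(d)
  if (length(unique(d[[predictor]])) < 2)
    stop("predictor '", predictor, "' is constant after complete-case filtering")
  adj <- c(covariates, extra_adjusters)
  rhs0 <- if (length(adj)) paste(sprintf("`%s`", adj), collapse = " + ") else "1"
  f0 <- stats::as.formula(paste(sprintf("`%s`", outcome), "~", rhs0))
  f1 <- stats::as.formula(paste(sprintf("`%s`", outcome), "~", rhs0, "+",
                                sprintf("`%s`", predictor)))
  m0 <- lm(f0, data = d)
  m1 <- lm(f1, data = d)
  if (n <= length(coef(m1))) stop("too few observations for the full model")
  a <- anova(m0, m1)
  r2 <- summary(m1)$r.squared - summary(m0)$r.squared
  data.frame(predictor = predictor, outcome = outcome, n = n,
             incremental_r2 = r2, statistic = a$F[2],
             df1 = a$Df[2], df2 = a$Res.Df[2], p = a$`Pr(>F)`[2],
             adjusted_pgs = length(extra_adjusters) > 0,
             stringsAsFactors = FALSE)
}

#' Proportional-odds (cumulative logit) regression
#'
#' Thin wrapper around [MASS::polr()] with the logistic link: ordered
#' intercepts, shared slopes, ML estimation. Returns the coefficient table
#' and the log-likelihood needed for pseudo-R-squared computation.
#'
#' @param data data frame.
#' @param outcome ordinal outcome column (integer categories or factor).
#' @param terms character vector of predictor columns (may be empty for the
#'   intercept-only model).
#' @return List: `coefficients` (slope table), `zeta` (thresholds),
#'   `logLik`, `n`, `fit` (the polr object).
#' @export
fit_proportional_odds <- function(data, outcome, terms = character()) {
  cols <- c(outcome, terms)
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols, drop = FALSE]
  y <- d[[outcome]]
  if (length(unique(y[!is.na(y)])) < 2)
    stop("outcome has fewer than 2 observed levels")
  d[[outcome]] <- factor(y, ordered = TRUE)
  rhs <- if (length(terms)) paste(sprintf("`%s`", terms), collapse = " + ") else "1"
  f <- stats::as.formula(paste(sprintf("`%s`", outcome), "~", rhs))
  if (nlevels(d[[outcome]]) == 2) {
    # two observed categories: the cumulative-logit model collapses to
    # ordinary logistic regression (zeta = -intercept, shared slopes equal)
    d$.y01 <- as.integer(d[[outcome]]) - 1L
    f2 <- stats::as.formula(paste(".y01 ~", rhs))
    gfit <- stats::glm(f2, data = d, family = stats::binomial())
    cf <- summary(gfit)$coefficients
    ct <- if (length(terms))
      data.frame(term = rownames(cf)[-1], estimate = cf[-1, 1], se = cf[-1, 2],
                 statistic = cf[-1, 3], p = cf[-1, 4], row.names = NULL,
                 stringsAsFactors = FALSE)
    else data.frame(term = character(), estimate = numeric(), se = numeric(),
                    statistic = numeric(), p = numeric())
    return(list(coefficients = ct,
                zeta = setNames(-cf[1, 1], "1|2"),
                logLik = as.numeric(logLik(gfit)), n = nrow(d), fit = gfit))
  }
  fit <- tryCatch(
    MASS::polr(f, data = d, Hess = TRUE, method = "logistic"),
    error = function(e) stop("proportional-odds fit failed (possible complete separation): ",
                             conditionMessage(e), call. = FALSE))
  ct <- if (length(terms)) {
    s <- summary(fit)$coefficients
    s <- s[seq_along(fit$coefficients), , drop = FALSE]
    data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
               statistic = s[, 3],
               p = 2 * pnorm(-abs(s[, 3])), row.names = NULL,
               stringsAsFactors = FALSE)
  } else data.frame(term = character(), estimate = numeric(), se = numeric(),
                    statistic = numeric(), p = numeric())
  list(coefficients = ct, zeta = fit$zeta,
       logLik = as.numeric(logLik(fit)), n = nrow(d), fit = fit)
}

#' Incremental Nagelkerke R-squared of a polygenic score on an ordinal trait
#'
#' Fits reduced (covariates) and full (covariates + score) proportional-odds
#' models on shared complete cases and computes, for each, the Nagelkerke
#' pseudo-R-squared
#' `[1 - exp((2/n)(LL0 - LL1))] / [1 - exp((2/n) LL0)]`
#' against the intercept-only model `LL0`; the incremental value is their
#' difference and the p-value comes from the 1-df likelihood-ratio test of
#' full versus reduced.
#'
#' @param data data frame.
#' @param outcome ordinal outcome column.
#' @param pgs score column name.
#' @param covariates covariate columns.
#' @return One-row data frame: `predictor`, `outcome`, `n`, `beta`, `se`,
#'   `incremental_r2` (Nagelkerke), `statistic` (LR chi-square), `p`.
#' @export
incremental_nagelkerke <- function(data, outcome, pgs, covariates = character()) {
  cols <- c(outcome, pgs, covariates)
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols, drop = FALSE]
  n <- nrow(d)
  null <- fit_proportional_odds(d, outcome, character())
  red <- fit_proportional_odds(d, outcome, covariates)
  full <- fit_proportional_odds(d, outcome, c(covariates, pgs))
  nag <- function(ll1) {
    (1 - exp((2 / n) * (null$logLik - ll1))) /
      (1 - exp((2 / n) * null$logLik))
  }
  inc <- nag(full$logLik) - nag(red$logLik)
  lr <- max(2 * (full$logLik - red$logLik), 0)
  slope <- full$coefficients[full$coefficients$term == sprintf("`%s`", pgs) |
                               full$coefficients$term == pgs, ]
  data.frame(predictor = pgs, outcome = outcome, n = n,
             beta = slope$estimate[1], se = slope$se[1],
             incremental_r2 = inc, statistic = lr,
             p = pchisq(lr, df = 1, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Bonferroni significance threshold
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error rate.
#' @return `alpha / n_tests`.
#' @export
bonferroni <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Effective number of independent tests by spectral decomposition
#'
#' Eigendecomposes a phenotype correlation matrix and summarises the
#' eigenvalue dispersion as an effective test count. `li_ji`:
#' `Meff = sum_i [ I(lambda_i >= 1) + (lambda_i - floor(lambda_i)) ]`;
#' `nyholt`: `Meff = 1 + (M - 1)(1 - Var(lambda) / M)`. The integer used
#' for thresholding is the ceiling of the raw value (conservative); the raw
#' value and eigenvalues are also returned.
#'
#' @param R correlation matrix of M phenotypes.
#' @param method `"li_ji"` (default) or `"nyholt"`.
#' @return List: `meff` (integer, ceiling), `raw`, `method`, `eigenvalues`.
#' @export
meff_spectral <- function(R, method = c("li_ji", "nyholt")) {
  method <- match.arg(method)
  stop_if_not_symmetric(R, "correlation matrix")
  M <- ncol(R)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  # guard the floor() in the Li-Ji sum against numerically negative zeros
  # and near-integer eigenvalues
  ev <- pmax(round(ev, 10), 0)
  raw <- switch(method,
    li_ji = sum(as.numeric(ev >= 1) + (ev - floor(ev))),
    nyholt = 1 + (M - 1) * (1 - stats::var(ev) / M))
  list(meff = as.integer(ceiling(raw - 1e-9)), raw = raw, method = method,
       eigenvalues = ev)
}

#' Keep predictors whose best incremental R-squared reaches a floor
#'
#' A predictor is retained iff its maximum incremental R-squared across all
#' screened outcomes is at least `min_max_r2` (default 1%, the rule under
#' which weak infant measures are dropped from multivariate modelling).
#'
#' @param screen data frame of [incremental_r2()] rows covering every
#'   predictor-outcome pair.
#' @param min_max_r2 retention floor (inclusive).
#' @return Character vector of retained predictor names.
#' @export
filter_predictors <- function(screen, min_max_r2 = 0.01) {
  if (!nrow(screen)) stop("empty screen table")
  mx <- tapply(screen$incremental_r2, screen$predictor, max)
  kept <- names(mx)[mx >= min_max_r2]
  if (!length(kept)) warning("no predictor reached the retention floor")
  kept
}

#' Power of a 1-df polygenic score association test
#'
#' Analytic power from the noncentral chi-square distribution with
#' noncentrality `NCP = n r2 / (1 - r2)`:
#' `power = P(chi2_1(NCP) > qchisq(1 - alpha, 1))`.
#'
#' @param n_target target-sample size.
#' @param r2 variance fraction explained by the score in the target sample.
#' @param alpha test level.
#' @return Power (numeric in `(0, 1)`).
#' @export
pgs_power <- function(n_target, r2, alpha = 0.05) {
  if (r2 <= 0 || r2 >= 1) stop("r2 must lie in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  ncp <- n_target * r2 / (1 - r2)
  pchisq(qchisq(1 - alpha, df = 1), df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Screen every predictor-outcome pair by incremental R-squared
#'
#' Convenience loop over [incremental_r2()] with per-pair complete cases,
#' returning the long-format screen table with Bonferroni pass flags.
#'
#' @param data cohort data frame.
#' @param predictors,outcomes column name vectors.
#' @param covariates covariate columns.
#' @param extra_adjusters columns adjusted for in both models (e.g. a
#'   confounder PGS).
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @return Data frame with one row per pair plus `pass_bonferroni`.
#' @export
screen_associations <- function(data, predictors, outcomes,
                                covariates = character(),
                                extra_adjusters = character(), alpha = 0.05) {
  rows <- list()
  for (pr in predictors) for (oc in outcomes)
    rows[[length(rows) + 1]] <-
      incremental_r2(data, oc, pr, covariates, extra_adjusters)
  out <- do.call(rbind, rows)
  thr <- bonferroni(nrow(out), alpha)
  out$pass_bonferroni <- out$p < thr
  attr(out, "threshold") <- thr
  out
}
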