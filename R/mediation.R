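#' Embed a polygenic score in a confirmed factor model
#'
#' Takes a confirmatory specification and adds the score as an observed
#' exogenous variable with free paths onto the predictor factor (`a`) and
#' onto every outcome factor (`b_<factor>`), replaces the
#' predictor-to-outcome factor correlations by directed paths
#' (`c_<factor>`, predictor to outcome, matching the temporal order of the
#' phenotypes), keeps the outcome-factor disturbances freely correlated and
#' the measurement part unchanged, and registers the defined parameters
#' `shared_<factor> = a * b_<factor>` and
#' `total_<factor> = a * b_<factor> + c_<factor>`.
#'
#' @param cfa_spec a [fm_spec()] from [cfa_spec()] / discovery.
#' @param pgs_name column name of the standardised score.
#' @param predictor_factor name of the (temporally first) factor.
#' @param outcome_factors names of the outcome factors (default: all other
#'   factors in the specification).
#' @return A [fm_spec()] with the mediation structure.
#' @export
build_mediation_spec <- function(cfa_spec, pgs_name, predictor_factor,
                                 outcome_factors = NULL) {
  stopifnot(inherits(cfa_spec, "fm_spec"))
  if (!predictor_factor %in% cfa_spec$latent)
    stop("unknown predictor factor: ", predictor_factor)
  if (is.null(outcome_factors))
    outcome_factors <- setdiff(cfa_spec$latent, predictor_factor)
  if (!all(outcome_factors %in% cfa_spec$latent))
    stop("unknown outcome factor(s): ",
         paste(setdiff(outcome_factors, cfa_spec$latent), collapse = ", "))
  spec <- fm_spec(observed = c(cfa_spec$observed, pgs_name),
                  latent = cfa_spec$latent)
  keep <- cfa_spec$vars
  for (m in c("free", "value", "label")) {
    spec$A[[m]][keep, keep] <- cfa_spec$A[[m]][keep, keep]
    spec$S[[m]][keep, keep] <- cfa_spec$S[[m]][keep, keep]
  }
  spec$defined <- cfa_spec$defined
  # exogenous score: free variance, paths a and b_k
  spec <- set_cov(spec, pgs_name, value = 1)
  spec <- set_path(spec, pgs_name, predictor_factor, value = 0.1, label = "a")
  for (f in outcome_factors) {
    spec <- set_path(spec, pgs_name, f, value = 0.1, label = paste0("b_", f))
    # replace the predictor<->outcome covariance with a directed path
    spec <- set_cov(spec, predictor_factor, f, free = FALSE, value = 0)
    spec <- set_path(spec, predictor_factor, f, value = 0.3,
                     label = paste0("c_", f))
    spec <- set_defined(spec, paste0("shared_", f),
                        sprintf("a * b_%s", f))
    spec <- set_defined(spec, paste0("total_", f),
                        sprintf("a * b_%s + c_%s", f, f))
  }
  spec
}

#' Estimate the shared/direct decomposition of factor associations
#'
#' Fits the PGS-embedded model by normal-theory ML on the complete cases,
#' reports the standardised `a`, `b_k`, `c_k`, `shared_k = a b_k` and
#' `total_k = a b_k + c_k` with delta-method (default) or bootstrap
#' standard errors and two-sided normal-approximation p-values, and checks
#' that the measurement part matches a PGS-free refit of the same
#' confirmatory structure within two standard errors.
#'
#' @param spec a specification from [build_mediation_spec()].
#' @param data data frame containing the observed measures and the
#'   (standardised) score column.
#' @param se_method `"delta"` or `"bootstrap"`.
#' @param B_boot bootstrap replicates when `se_method = "bootstrap"`.
#' @param seed RNG seed.
#' @return Object of class `mediation_result`: `effects` (data frame with
#'   a/b/c/shared/total rows), `fit` (the `fm_fit`), `loading_check`
#'   (comparison against the PGS-free model), `se_method`.
#' @export
estimate_effects <- function(spec, data, se_method = c("delta", "bootstrap"),
                             B_boot = 500, seed = 1) {
  se_method <- match.arg(se_method)
  stopifnot(inherits(spec, "fm_spec"))
  obs <- spec$observed
  d <- data[stats::complete.cases(data[, obs, drop = FALSE]), obs, drop = FALSE]
  n <- nrow(d)
  pgs_name <- obs[length(obs)]
  # collinearity guard: the score must not be (near-)collinear with another
  # observed variable
  R <- stats::cor(d)
  off <- R[pgs_name, setdiff(obs, pgs_name)]
  if (any(abs(off) > 0.999))
    stop("score column is collinear with an observed variable")
  fit <- fit_ml(spec, stats::cov(d), n, seed = seed)
  if (!fit$converged) stop("mediation model did not converge")
  std <- standardize(fit)
  labs <- std$parameter
  eff_rows <- std[grepl("^(a$|b_|c_|shared_|total_)", labs), , drop = FALSE]
  # Sobel form of the product SE (no covariance term), reported alongside
  sob <- setNames(rep(NA_real_, nrow(eff_rows)), eff_rows$parameter)
  a_est <- std$est_std[std$parameter == "a"]
  a_se <- std$se_std[std$parameter == "a"]
  for (nm in eff_rows$parameter[grepl("^shared_", eff_rows$parameter)]) {
    f <- sub("^shared_", "", nm)
    b_est <- std$est_std[std$parameter == paste0("b_", f)]
    b_se <- std$se_std[std$parameter == paste0("b_", f)]
    sob[nm] <- sqrt(a_est^2 * b_se^2 + b_est^2 * a_se^2)
  }
  eff_rows$se_sobel <- unname(sob)
  if (se_method == "bootstrap") {
    boot <- bootstrap_se(d, spec, B = B_boot, seed = child_seed(seed, "medboot"))
    m <- match(eff_rows$parameter, names(boot$se))
    eff_rows$se_boot <- boot$se[m]
  }
  # measurement-invariance check against the PGS-free confirmatory refit
  cfa <- strip_pgs_spec(spec, pgs_name)
  cfa_fit <- tryCatch(
    fit_ml(cfa, stats::cov(d[, cfa$observed, drop = FALSE]), n, seed = seed),
    error = function(e) NULL)
  loading_check <- NULL
  if (!is.null(cfa_fit) && cfa_fit$converged && cfa_fit$admissible) {
    s0 <- standardize(cfa_fit)
    lo <- grepl("=~", s0$parameter)
    m <- match(s0$parameter[lo], std$parameter)
    loading_check <- data.frame(
      parameter = s0$parameter[lo],
      cfa = s0$est_std[lo], mediation = std$est_std[m],
      within_2se = abs(s0$est_std[lo] - std$est_std[m]) <=
        2 * pmax(s0$se_std[lo], std$se_std[m]),
      stringsAsFactors = FALSE)
  }
  out <- list(effects = eff_rows, fit = fit, loading_check = loading_check,
              se_method = se_method, n = n)
  class(out) <- "mediation_result"
  out
}

# Remove the exogenous score from a mediation specification, restoring the
# plain confirmatory model (directed predictor->outcome paths retained as
# free covariances).
strip_pgs_spec <- function(spec, pgs_name) {
  keep_obs <- setdiff(spec$observed, pgs_name)
  out <- fm_spec(observed = keep_obs, latent = spec$latent)
  keep <- out$vars
  for (m in c("free", "value", "label")) {
    out$A[[m]][keep, keep] <- spec$A[[m]][keep, keep]
    out$S[[m]][keep, keep] <- spec$S[[m]][keep, keep]
  }
  # convert factor-to-factor directed paths back to covariances
  lat <- out$latent
  for (f1 in lat) for (f2 in lat) {
    if (out$A$free[f2, f1]) {
      out$A$free[f2, f1] <- FALSE
      out$A$value[f2, f1] <- 0
      out$A$label[f2, f1] <- ""
      out <- set_cov(out, f1, f2, value = 0.2)
    }
  }
  out$defined <- character()
  out
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("PGS-embedded mediation decomposition (n =", x$n, ")\n")
  print(x$effects, digits = 3, row.names = FALSE)
  if (!is.null(x$loading_check))
    cat("loadings within 2 SE of the PGS-free model:",
        sum(x$loading_check$within_2se), "of", nrow(x$loading_check), "\n")
  invisible(x)
}
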