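#' Fit a covariance-structure model by normal-theory maximum likelihood
#'
#' Minimises the ML discrepancy
#' `F_ML = log|Sigma(theta)| + tr(S Sigma(theta)^-1) - log|S| - p`
#' over the free parameters of `spec`, from multiple jittered starts, and
#' returns estimates, standard errors from the inverse Hessian, the chi-square
#' statistic `T = (n-1) F_ML`, baseline (independence-model) statistic, fit
#' indices and the standardised solution.
#'
#' Identification is checked before optimisation: the model must have
#' non-negative degrees of freedom and every latent variable must be anchored
#' by a fixed variance or a fixed nonzero incoming path.
#'
#' @param spec a [fm_spec()].
#' @param S sample covariance matrix of the observed variables (symmetric
#'   positive definite, dimnames matching `spec$observed`).
#' @param n number of observations behind `S`.
#' @param restarts number of jittered restarts (first start is unjittered).
#' @param seed seed controlling the jitter stream.
#' @param control list passed to [stats::nlminb()]; the default tightens the
#'   relative tolerance to `1e-10`.
#' @return Object of class `fm_fit`: estimates, `se`, `acov`, discrepancy
#'   `F_ml`, statistic `T`, `df`, baseline `T0`/`df0`, `indices` (CFI, TLI,
#'   RMSEA, SRMR), `std` (standardised solution with delta-method SEs,
#'   including defined parameters), convergence and admissibility flags.
#' @export
fit_ml <- function(spec, S, n, restarts = 5, seed = 1, control = list()) {
  stopifnot(inherits(spec, "fm_spec"))
  p <- length(spec$observed)
  stop_if_not_symmetric(S, "sample covariance")
  if (is.null(dimnames(S))) dimnames(S) <- list(spec$observed, spec$observed)
  S <- S[spec$observed, spec$observed]
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop(sprintf("sample covariance is not positive definite (smallest eigenvalue %.3g)",
                 min(ev)), call. = FALSE)
  if (n <= p) stop("n must exceed the number of observed variables")

  tab <- param_table(spec)
  q <- nrow(tab)
  df <- p * (p + 1) / 2 - q
  for (f in spec$latent) {
    anchored <- (!spec$S$free[f, f] && spec$S$value[f, f] > 0) ||
      any(!spec$A$free[, f] & spec$A$value[, f] != 0)
    if (!anchored)
      stop("latent variable '", f, "' has no scale anchor (fix its variance ",
           "or one loading)", call. = FALSE)
  }
  if (df < 0)
    stop(sprintf("model not identified: %d free parameters for %d moments",
                 q, p * (p + 1) / 2), call. = FALSE)

  logdetS <- determinant(S, logarithm = TRUE)$modulus
  objective <- function(theta) {
    names(theta) <- tab$label
    Sigma <- tryCatch(
      implied_moments(spec, theta)[spec$observed, spec$observed],
      error = function(e) NULL)
    if (is.null(Sigma)) return(1e10)
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdet <- 2 * sum(log(diag(ch)))
    tr <- sum(diag(chol2inv(ch) %*% S))
    val <- logdet + tr - logdetS - p
    if (!is.finite(val)) 1e10 else as.numeric(val)
  }

  ctl <- modifyList(list(rel.tol = 1e-10, iter.max = 500, eval.max = 2000),
                    control)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(max(1, restarts))) {
      start <- tab$start
      if (r > 1) start <- start + rnorm(q, 0, 0.2)
      start <- pmax(start, tab$lower + 1e-4)
      opt <- tryCatch(
        stats::nlminb(start, objective, lower = tab$lower, control = ctl),
        error = function(e) NULL)
      if (is.null(opt)) next
      if (is.null(best) || opt$objective < best$objective - 1e-12) best <- opt
    }
  })
  if (is.null(best)) stop("optimisation failed in every restart")

  theta <- setNames(best$par, tab$label)
  F_ml <- max(best$objective, 0)
  if (F_ml < 1e-10) F_ml <- 0          # numerically saturated
  Tstat <- (n - 1) * F_ml

  # nlminb flags "false/relative-function convergence" at flat optima; accept
  # any stationary point with a numerically vanishing scaled gradient
  converged <- best$convergence == 0
  if (!converged) {
    gr <- pracma::grad(objective, best$par)
    converged <- max(abs(gr)) < 1e-4 * max(1, abs(best$objective))
  }

  # baseline (independence) model: Sigma0 = diag(S), closed form
  F0 <- sum(log(diag(S))) - logdetS
  T0 <- (n - 1) * F0
  df0 <- p * (p - 1) / 2

  # asymptotic covariance of the estimates from the Hessian of F_ML
  H <- pracma::hessian(objective, best$par)
  acov <- tryCatch((2 / (n - 1)) * solve((H + t(H)) / 2),
                   error = function(e) (2 / (n - 1)) * pracma::pinv((H + t(H)) / 2))
  dimnames(acov) <- list(tab$label, tab$label)
  se <- sqrt(pmax(diag(acov), 0))

  Sigma <- implied_covariance(spec, theta)
  Vfull <- implied_moments(spec, theta)
  admissible <- all(diag(Vfull) > 0) &&
    all(theta[tab$label[tab$lower > -Inf]] > 1e-5)

  fit <- list(spec = spec, est = theta, se = se, acov = acov,
              F_ml = F_ml, T = Tstat, df = df, T0 = T0, df0 = df0, n = n,
              S = S, Sigma = Sigma,
              converged = converged, admissible = admissible)
  fit$indices <- fit_indices(Tstat, df, T0, df0, n, S, Sigma)
  fit$std <- if (admissible) standardized_table(fit) else NULL
  class(fit) <- "fm_fit"
  fit
}

#' Incremental and absolute fit indices
#'
#' `CFI = 1 - max(T - df, 0) / max(T0 - df0, T - df, 0)` (capped to `[0,1]`),
#' `TLI = (T0/df0 - T/df) / (T0/df0 - 1)` (uncapped),
#' `RMSEA = sqrt(max(T - df, 0) / (df (n-1)))`, and SRMR is the root mean
#' square of residual correlations between the standardised sample and
#' implied matrices over the lower triangle including the diagonal. With
#' `df = 0`, TLI and RMSEA are undefined and returned as `NA`.
#'
#' @param T,df test statistic and degrees of freedom of the fitted model.
#' @param T0,df0 statistic and df of the baseline independence model.
#' @param n sample size.
#' @param S,Sigma sample and implied covariance matrices (for SRMR); may be
#'   `NULL`, in which case SRMR is `NA`.
#' @return Named numeric vector `c(CFI, TLI, RMSEA, SRMR)`.
#' @export
fit_indices <- function(T, df, T0, df0, n, S = NULL, Sigma = NULL) {
  stopifnot(T >= 0, T0 >= 0, df >= 0, df0 >= df)
  denom <- max(T0 - df0, T - df, 0)
  cfi <- if (denom == 0) 1 else 1 - max(T - df, 0) / denom
  cfi <- min(max(cfi, 0), 1)
  if (df > 0 && df0 > 0) {
    tli <- (T0 / df0 - T / df) / (T0 / df0 - 1)
    rmsea <- sqrt(max(T - df, 0) / (df * (n - 1)))
  } else {
    tli <- NA_real_; rmsea <- NA_real_
  }
  srmr <- NA_real_
  if (!is.null(S) && !is.null(Sigma)) {
    d <- sqrt(diag(S))
    res <- (S - Sigma) / tcrossprod(d)
    srmr <- sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))
  }
  c(CFI = cfi, TLI = tli, RMSEA = rmsea, SRMR = srmr)
}

# Standardised value of every free parameter at a parameter point, plus
# defined parameters evaluated on the standardised estimates.
standardize_at <- function(spec, theta) {
  V <- implied_moments(spec, theta)
  sdv <- sqrt(pmax(diag(V), .Machine$double.eps))
  m <- fill_matrices(spec, theta)
  out <- numeric(0)
  idx <- which(spec$A$free, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]   # path j -> i
    out[spec$A$label[i, j]] <- m$A[i, j] * sdv[j] / sdv[i]
  }
  idx <- which(spec$S$free & upper.tri(spec$S$free, diag = TRUE), arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    out[spec$S$label[i, j]] <- m$S[i, j] / (sdv[i] * sdv[j])
  }
  out <- out[!duplicated(names(out))]
  if (length(spec$defined)) {
    vals <- as.list(out)
    for (nm in names(spec$defined))
      out[nm] <- eval(parse(text = spec$defined[nm]), envir = vals,
                      enclos = baseenv())
  }
  out
}

# Standardised solution with delta-method SEs propagated through the
# standardisation map (numeric jacobian times the ML parameter covariance).
standardized_table <- function(fit) {
  spec <- fit$spec
  labs <- names(fit$est)
  g <- function(th) {
    names(th) <- labs
    standardize_at(spec, th)
  }
  std <- g(fit$est)
  J <- pracma::jacobian(g, fit$est)
  vs <- diag(J %*% fit$acov %*% t(J))
  data.frame(parameter = names(std), est_std = as.numeric(std),
             se_std = sqrt(pmax(vs, 0)),
             z = as.numeric(std) / sqrt(pmax(vs, 1e-300)),
             p = 2 * pnorm(-abs(as.numeric(std) / sqrt(pmax(vs, 1e-300)))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Standardised solution of a fitted model
#'
#' Rescales every estimate by the model-implied standard deviations so that
#' loadings and paths are in correlation metric and factor covariances become
#' correlations; defined parameters are recomputed from the standardised
#' estimates. Requires an admissible solution.
#'
#' @param fit a `fm_fit` from [fit_ml()].
#' @return Data frame with columns `parameter`, `est_std`, `se_std`, `z`, `p`.
#' @export
standardize <- function(fit) {
  stopifnot(inherits(fit, "fm_fit"))
  if (!fit$admissible)
    stop("solution is not admissible; standardised estimates withheld")
  fit$std %||% standardized_table(fit)
}

#' Bootstrap standard errors for a covariance-structure model
#'
#' Nonparametric case resampling: individuals are resampled with
#' replacement, the model refitted on each replicate covariance, and the SE
#' taken as the standard deviation of converged replicate estimates
#' (standardised solution). Replicate non-convergence is counted; more than
#' 50% failures aborts with diagnostics.
#'
#' @param data data frame (rows = individuals) containing `spec$observed`;
#'   complete cases are used.
#' @param spec a [fm_spec()].
#' @param B number of bootstrap replicates (>= 2).
#' @param seed RNG seed for resampling.
#' @param conf percentile interval coverage.
#' @return List with `se` (named vector over standardised parameters and
#'   defined quantities), `ci` (percentile bounds), `n_failed`, `B`.
#' @export
bootstrap_se <- function(data, spec, B = 1000, seed = 1, conf = 0.95) {
  stopifnot(inherits(spec, "fm_spec"), B >= 2)
  data <- data[stats::complete.cases(data[, spec$observed, drop = FALSE]), , drop = FALSE]
  n <- nrow(data)
  if (n <= length(spec$observed) + 1)
    stop("too few complete cases to bootstrap (n = ", n, ")")
  X <- as.matrix(data[, spec$observed, drop = FALSE])
  reps <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      Sb <- stats::cov(X[idx, , drop = FALSE])
      tryCatch({
        fb <- fit_ml(spec, Sb, n, restarts = 1, seed = b)
        if (!fb$converged || is.null(fb$std)) NULL else
          setNames(fb$std$est_std, fb$std$parameter)
      }, error = function(e) NULL)
    })
  })
  failed <- sum(vapply(reps, is.null, TRUE))
  if (failed > B / 2)
    stop(sprintf("bootstrap failed: %d of %d replicates did not converge",
                 failed, B))
  mat <- do.call(rbind, reps[!vapply(reps, is.null, TRUE)])
  a <- (1 - conf) / 2
  list(se = apply(mat, 2, stats::sd),
       ci = t(apply(mat, 2, stats::quantile, probs = c(a, 1 - a))),
       n_failed = failed, B = B)
}

#' @export
print.fm_fit <- function(x, ...) {
  cat("Covariance-structure model fit (normal-theory ML)\n")
  cat(sprintf("  n = %d, T = %.3f, df = %d, converged: %s, admissible: %s\n",
              x$n, x$T, x$df, x$converged, x$admissible))
  cat(sprintf("  CFI = %.3f  TLI = %.3f  RMSEA = %.3f  SRMR = %.3f\n",
              x$indices["CFI"], x$indices["TLI"], x$indices["RMSEA"],
              x$indices["SRMR"]))
  if (!is.null(x$std)) {
    cat("  standardised solution:\n")
    print(utils::head(x$std, 30), digits = 3)
  }
  invisible(x)
}
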