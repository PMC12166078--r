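#' @keywords internal
"_PACKAGE"

#' @importFrom stats anova aov coef complete.cases cor cov cov2cor dnorm lm
#'   logLik na.omit optim pchisq pf pnorm qchisq qlogis qnorm quantile rbinom
#'   resid rnorm runif sd setNames var
#' @importFrom utils head read.delim write.table
NULL

# Run code with a temporary RNG state seeded by `seed`, restoring the caller's
# stream afterwards so library functions never perturb user-level randomness.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a reproducible child seed from a master seed and a stream tag,
# staying inside the 32-bit integer range.
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

stop_if_not_symmetric <- function(m, name = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop(sprintf("%s must be a symmetric square matrix", name), call. = FALSE)
  invisible(m)
}

# Symmetric PSD check with an informative eigenvalue in the message.
check_psd <- function(m, name = "matrix", tol = 1e-8) {
  stop_if_not_symmetric(m, name)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol)
    stop(sprintf("%s is not positive semi-definite (smallest eigenvalue %.3g)",
                 name, min(ev)), call. = FALSE)
  invisible(ev)
}

# Multivariate normal draws via Cholesky with PSD fallback through the
# eigendecomposition (rank-deficient covariances are legal for generators).
rmvn <- function(n, sigma) {
  p <- ncol(sigma)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    eg <- eigen(sigma, symmetric = TRUE)
    ch <- t(eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), p))
  }
  matrix(rnorm(n * p), n, p) %*% ch
}

`%||%` <- function(a, b) if (is.null(a)) b else a
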