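#' Declarative covariance-structure model specification
#'
#' A `fm_spec` holds a structural equation model in reticular-action form:
#' directed paths (factor loadings, regressions) in a matrix `A` and
#' symmetric (co)variances in a matrix `S`, both indexed over observed plus
#' latent variables. The model-implied covariance of the observed variables
#' is `F (I - A)^-1 S (I - A)^-T F'`. Free entries carry parameter labels;
#' entries sharing a label are constrained equal. Named *defined parameters*
#' (arithmetic expressions in the labels, e.g. products `a*b`) are evaluated
#' from the point estimates after fitting.
#'
#' @param observed character vector of observed-variable names.
#' @param latent character vector of latent-variable names.
#' @return An object of class `fm_spec`.
#' @seealso [cfa_spec()] for the common confirmatory-factor layout,
#'   [set_path()], [set_cov()], [set_defined()] for incremental edits.
#' @export
fm_spec <- function(observed, latent = character()) {
  vars <- c(observed, latent)
  if (anyDuplicated(vars)) stop("variable names must be unique")
  nv <- length(vars)
  zero <- matrix(0, nv, nv, dimnames = list(vars, vars))
  lab <- matrix("", nv, nv, dimnames = list(vars, vars))
  spec <- list(
    observed = observed, latent = latent, vars = vars,
    A = list(free = zero > 1, value = zero, label = lab),
    S = list(free = zero > 1, value = zero, label = lab),
    defined = character()
  )
  class(spec) <- "fm_spec"
  spec
}

#' Add or fix a directed path
#'
#' @param spec a [fm_spec()].
#' @param from,to variable names; the path points `from -> to` (for a factor
#'   loading, `from` is the factor and `to` the indicator).
#' @param free logical; free parameter (default) or fixed.
#' @param value start value if free, fixed value otherwise.
#' @param label parameter label; defaults to `"to~from"` (loadings print as
#'   `"factor=~item"`). Reusing a label imposes an equality constraint.
#' @export
set_path <- function(spec, from, to, free = TRUE, value = if (free) 0.3 else 0,
                     label = NULL) {
  stopifnot(inherits(spec, "fm_spec"))
  for (v in c(from, to)) if (!v %in% spec$vars) stop("unknown variable: ", v)
  if (is.null(label))
    label <- if (from %in% spec$latent && to %in% spec$observed)
      paste0(from, "=~", to) else paste0(to, "~", from)
  spec$A$free[to, from] <- free
  spec$A$value[to, from] <- value
  spec$A$label[to, from] <- if (free) label else ""
  spec
}

#' Add or fix a variance or covariance
#'
#' @inheritParams set_path
#' @param a,b variable names (equal for a variance).
#' @export
set_cov <- function(spec, a, b = a, free = TRUE, value = if (free) 0.5 else 0,
                    label = NULL) {
  stopifnot(inherits(spec, "fm_spec"))
  for (v in c(a, b)) if (!v %in% spec$vars) stop("unknown variable: ", v)
  if (is.null(label)) label <- paste0(a, "~~", b)
  spec$S$free[a, b] <- spec$S$free[b, a] <- free
  spec$S$value[a, b] <- spec$S$value[b, a] <- value
  spec$S$label[a, b] <- spec$S$label[b, a] <- if (free) label else ""
  spec
}

#' Register a defined parameter
#'
#' @inheritParams set_path
#' @param name name of the derived quantity.
#' @param expr character; an arithmetic expression in existing parameter
#'   labels, e.g. `"a * b_speech + c_speech"`.
#' @export
set_defined <- function(spec, name, expr) {
  stopifnot(inherits(spec, "fm_spec"))
  spec$defined[name] <- expr
  spec
}

#' Confirmatory factor model specification
#'
#' Builds the standard CFA layout: simple- or cross-loading measurement
#' pattern, unit-variance (standardised) factors, freely correlated factors,
#' and free uncorrelated residuals.
#'
#' @param loadings either a named list mapping factor names to character
#'   vectors of indicator names, or a numeric items-by-factors matrix with
#'   zeros for fixed-zero entries and nonzero start values for free loadings
#'   (dimnames required).
#' @param correlated_factors logical; free all pairwise factor covariances
#'   (default `TRUE`).
#' @return A [fm_spec()].
#' @export
cfa_spec <- function(loadings, correlated_factors = TRUE) {
  if (is.list(loadings)) {
    factors <- names(loadings)
    items <- unique(unlist(loadings))
    L <- matrix(0, length(items), length(factors),
                dimnames = list(items, factors))
    for (f in factors) L[loadings[[f]], f] <- 0.5
  } else {
    L <- as.matrix(loadings)
    if (is.null(rownames(L)) || is.null(colnames(L)))
      stop("loading matrix needs item and factor dimnames")
    items <- rownames(L); factors <- colnames(L)
  }
  spec <- fm_spec(observed = items, latent = factors)
  for (f in factors) {
    spec <- set_cov(spec, f, free = FALSE, value = 1)  # standardised factors
    for (i in items[L[, f] != 0])
      spec <- set_path(spec, f, i, value = L[i, f])
  }
  if (correlated_factors && length(factors) > 1) {
    pairs <- utils::combn(factors, 2)
    for (k in seq_len(ncol(pairs)))
      spec <- set_cov(spec, pairs[1, k], pairs[2, k], value = 0.2)
  }
  for (i in items) spec <- set_cov(spec, i, value = 0.5)
  spec
}

# Unique free-parameter table: label, start value, lower bound (variances
# bounded away from the boundary so nlminb stays in the PD region).
param_table <- function(spec) {
  entries <- list()
  add <- function(mat, which) {
    idx <- which(mat$free, arr.ind = TRUE)
    if (which == "S") idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      entries[[length(entries) + 1]] <<- data.frame(
        label = mat$label[i, j], start = mat$value[i, j],
        lower = if (which == "S" && i == j) 1e-6 else -Inf,
        stringsAsFactors = FALSE)
    }
  }
  add(spec$A, "A"); add(spec$S, "S")
  tab <- do.call(rbind, entries)
  if (is.null(tab)) return(data.frame(label = character(), start = numeric(),
                                      lower = numeric()))
  # first occurrence wins for start; lower bound is the tightest across uses
  agg <- tab[!duplicated(tab$label), ]
  agg$lower <- vapply(agg$label, function(l) max(tab$lower[tab$label == l]), 0)
  rownames(agg) <- NULL
  agg
}

n_free_params <- function(spec) nrow(param_table(spec))

# Substitute a named parameter vector into the A and S matrices.
fill_matrices <- function(spec, params) {
  A <- spec$A$value; S <- spec$S$value
  if (any(spec$A$free)) {
    idx <- which(spec$A$free)
    A[idx] <- params[spec$A$label[idx]]
  }
  if (any(spec$S$free)) {
    idx <- which(spec$S$free)
    S[idx] <- params[spec$S$label[idx]]
  }
  list(A = A, S = S)
}

# Full implied moment matrix over observed + latent variables.
implied_moments <- function(spec, params) {
  m <- fill_matrices(spec, params)
  I <- diag(length(spec$vars))
  B <- solve(I - m$A)
  V <- B %*% m$S %*% t(B)
  dimnames(V) <- list(spec$vars, spec$vars)
  (V + t(V)) / 2
}

#' Model-implied covariance matrix
#'
#' Computes the covariance matrix of the observed variables implied by a
#' specification at a given parameter point. For a pure CFA this equals
#' `Lambda Psi Lambda' + Theta`.
#'
#' @param spec a [fm_spec()].
#' @param params named numeric vector covering every free parameter label.
#' @return Symmetric covariance matrix over `spec$observed`.
#' @export
implied_covariance <- function(spec, params) {
  stopifnot(inherits(spec, "fm_spec"))
  tab <- param_table(spec)
  params <- unlist(params)
  missing <- setdiff(tab$label, names(params))
  if (length(missing))
    stop("parameter vector does not cover free parameters: ",
         paste(missing, collapse = ", "))
  implied_moments(spec, params)[spec$observed, spec$observed, drop = FALSE]
}

#' @export
print.fm_spec <- function(x, ...) {
  cat("Covariance-structure model specification\n")
  cat("  observed:", length(x$observed), "  latent:", length(x$latent),
      "  free parameters:", n_free_params(x), "\n")
  if (length(x$defined))
    cat("  defined:", paste(names(x$defined), collapse = ", "), "\n")
  invisible(x)
}

#' Reference three-factor developmental model
#'
#' The standardised three-factor confirmatory model linking preschool
#' musicality items (sing three songs, hum a tune, clap to a beat, age 5) to
#' school-age verbal cognition (nonword repetition, verbal IQ, age 9;
#' appropriate initiation, age 10) and speech-related communication
#' (intelligibility/fluency, syntax, conversational rapport, age 10).
#' Loadings and factor correlations are the published standardised
#' estimates; residual variances are `1 - lambda^2` so every observed
#' variable has unit variance.
#'
#' @return List with elements `spec` (a [fm_spec()]), `params` (the named
#'   generating parameter vector), `sigma` (the implied correlation matrix)
#'   and `loadings`/`factor_cor` (the generating matrices).
#' @export
stage3_model <- function() {
  items <- c("sing_5y", "hum_5y", "clap_5y",
             "nonword_9y", "verbiq_9y", "initiation_10y",
             "intelligibility_10y", "syntax_10y", "rapport_10y")
  factors <- c("musicality", "cognition", "speech")
  L <- matrix(0, 9, 3, dimnames = list(items, factors))
  L[1:3, "musicality"] <- c(0.55, 0.74, 0.54)
  L[4:6, "cognition"]  <- c(0.61, 0.64, 0.20)
  L[7:9, "speech"]     <- c(0.55, 0.59, 0.40)
  P <- matrix(c(1, 0.31, 0.42,
                0.31, 1, 0.56,
                0.42, 0.56, 1), 3, 3, dimnames = list(factors, factors))
  spec <- cfa_spec(L)
  params <- numeric(0)
  for (f in factors) for (i in items[L[, f] != 0])
    params[paste0(f, "=~", i)] <- L[i, f]
  params["musicality~~cognition"] <- P["musicality", "cognition"]
  params["musicality~~speech"] <- P["musicality", "speech"]
  params["cognition~~speech"] <- P["cognition", "speech"]
  for (i in items) params[paste0(i, "~~", i)] <- 1 - sum(L[i, ]^2)
  sigma <- implied_covariance(spec, params)
  list(spec = spec, params = params, sigma = sigma, loadings = L,
       factor_cor = P)
}
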