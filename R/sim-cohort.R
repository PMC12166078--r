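#' Simulation configuration for a synthetic developmental cohort
#'
#' Bundles and validates everything the cohort generator needs: the
#' generating factor structure (standardised loadings and factor
#' correlations), per-item ordinal category probabilities, per-factor
#' standardised polygenic-score paths, covariate effects and per-measure
#' missingness rates. Total variance of every measure is 1 before
#' ordinalisation, so `lambda^2` plus the PGS-path contribution must leave a
#' nonnegative residual.
#'
#' @param n_individuals cohort size.
#' @param seed master RNG seed.
#' @param loading_matrix numeric items-by-factors matrix of standardised
#'   loadings in `[-1, 1]` (dimnames required).
#' @param factor_correlations symmetric PSD matrix with unit diagonal.
#' @param ordinal_specs named list: per ordinal item, a length-3 vector of
#'   category probabilities (summing to 1). Items absent from the list are
#'   generated as continuous measures.
#' @param pgs_paths named numeric vector of standardised PGS-on-factor path
#'   coefficients (names are factor names; default all zero).
#' @param measure_roles named character vector, `"predictor"` or
#'   `"outcome"` per item; defaults to `"predictor"` for items loading the
#'   first factor and `"outcome"` otherwise.
#' @param missing_rates named per-measure missingness fractions in `[0, 1)`.
#' @param covariate_effects optional named list: per measure, a numeric
#'   vector of coefficients for `(sex, age, PC1..PC10)`; defaults to zero.
#' @param n_snps,maf_range genotype panel size and minor-allele-frequency
#'   range for the paired genotype generator.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals, seed = 1, loading_matrix,
                       factor_correlations, ordinal_specs = list(),
                       pgs_paths = NULL, measure_roles = NULL,
                       missing_rates = NULL, covariate_effects = list(),
                       n_snps = 1000, maf_range = c(0.05, 0.5)) {
  L <- as.matrix(loading_matrix)
  if (is.null(rownames(L)) || is.null(colnames(L)))
    stop("loading_matrix needs item and factor dimnames")
  if (any(abs(L) > 1)) stop("loadings must lie in [-1, 1]")
  P <- as.matrix(factor_correlations)
  if (any(abs(diag(P) - 1) > 1e-8))
    stop("factor_correlations must have unit diagonal")
  ev <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("factor correlation matrix is not positive semi-definite (smallest eigenvalue %.3g)",
                 min(ev)), call. = FALSE)
  dimnames(P) <- list(colnames(L), colnames(L))
  a <- setNames(rep(0, ncol(L)), colnames(L))
  if (!is.null(pgs_paths)) a[names(pgs_paths)] <- pgs_paths
  resid_psi <- P - tcrossprod(a)
  if (min(eigen(resid_psi, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("pgs_paths too large: residual factor covariance not PSD")
  comm <- rowSums((L %*% P) * L)
  if (any(comm > 1 + 1e-8))
    stop("item communality exceeds 1; reduce loadings")
  for (nm in names(ordinal_specs)) {
    pr <- ordinal_specs[[nm]]
    if (length(pr) != 3 || abs(sum(pr) - 1) > 1e-8 || any(pr < 0))
      stop("ordinal_specs[['", nm, "']] must be 3 nonnegative probabilities summing to 1")
    if (!nm %in% rownames(L)) stop("ordinal spec for unknown measure ", nm)
  }
  if (is.null(measure_roles)) {
    measure_roles <- ifelse(L[, 1] != 0, "predictor", "outcome")
    names(measure_roles) <- rownames(L)
  }
  mr <- setNames(rep(0, nrow(L)), rownames(L))
  if (!is.null(missing_rates)) {
    if (any(missing_rates < 0 | missing_rates >= 1))
      stop("missing_rates must lie in [0, 1)")
    mr[names(missing_rates)] <- missing_rates
  }
  structure(list(
    n_individuals = n_individuals, seed = seed, loading_matrix = L,
    factor_names = colnames(L), factor_correlations = P,
    ordinal_specs = ordinal_specs, pgs_paths = a,
    measure_roles = measure_roles, missing_rates = mr,
    covariate_effects = covariate_effects,
    n_snps = n_snps, maf_range = maf_range), class = "sim_config")
}

#' Threshold a latent continuous vector into three ordered categories
#'
#' Category thresholds are placed at the latent distribution's quantiles of
#' the cumulative probabilities, so empirical frequencies converge to the
#' requested probabilities. A zero-probability middle category collapses the
#' scale to two levels with a warning.
#'
#' @param latent numeric vector (missing values propagate).
#' @param category_probs length-3 probabilities summing to 1.
#' @return Integer vector with values in `{1, 2, 3}`.
#' @export
ordinalize <- function(latent, category_probs) {
  if (length(category_probs) != 3 || abs(sum(category_probs) - 1) > 1e-8 ||
      any(category_probs < 0))
    stop("category_probs must be 3 nonnegative probabilities summing to 1")
  if (category_probs[2] == 0)
    warning("middle category has probability 0; output collapses to 2 levels")
  cuts <- stats::quantile(latent, probs = cumsum(category_probs)[1:2],
                          na.rm = TRUE, names = FALSE, type = 7)
  out <- rep(NA_integer_, length(latent))
  ok <- !is.na(latent)
  out[ok] <- 1L + (latent[ok] > cuts[1]) + (latent[ok] > cuts[2])
  attr(out, "thresholds") <- cuts
  out
}

#' Generate a synthetic cohort with latent factor structure
#'
#' Draws factor scores from a multivariate normal with the configured
#' correlations (optionally partly driven by a supplied standardised PGS
#' through the per-factor paths), builds each measure as
#' `lambda * factor + covariate effects + residual` with residual variance
#' scaled so the systematic-plus-residual variance is 1, then ordinalises
#' items that carry a category specification. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param pgs optional standardised score vector of length `n_individuals`
#'   feeding the configured `pgs_paths`.
#' @return Data frame (`cohort` class) with `individual_id`, covariates
#'   (`sex`, `age`, `PC1..PC10`), one column per measure, and a `meta`
#'   attribute (data frame: measure, role, type, categories).
#' @export
generate_cohort <- function(config, pgs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  L <- config$loading_matrix
  P <- config$factor_correlations
  a <- config$pgs_paths
  if (is.null(pgs)) {
    if (any(a != 0)) stop("config has nonzero pgs_paths but no pgs supplied")
    pgs <- numeric(n)
  }
  stopifnot(length(pgs) == n)

  with_seed(config$seed, {
    sex <- rbinom(n, 1, 0.51)
    age <- rnorm(n, 4.78, 0.07)
    pcs <- matrix(rnorm(n * 10, 0, 1), n, 10,
                  dimnames = list(NULL, paste0("PC", 1:10)))
    eta <- pgs %*% t(a) + rmvn(n, P - tcrossprod(a))
    colnames(eta) <- config$factor_names
    covars <- cbind(sex = sex, age = age, pcs)
    meas <- matrix(NA_real_, n, nrow(L), dimnames = list(NULL, rownames(L)))
    for (i in rownames(L)) {
      sys <- as.numeric(eta %*% L[i, ])
      beta <- config$covariate_effects[[i]]
      if (!is.null(beta)) sys <- sys + as.numeric(covars %*% beta)
      comm <- sum((L[i, ] %*% P) * L[i, ])
      meas[, i] <- sys + rnorm(n, 0, sqrt(max(1 - comm, 0)))
    }
    df <- data.frame(individual_id = sprintf("id%06d", seq_len(n)),
                     sex = sex, age = age, pcs, check.names = FALSE)
    types <- character(0)
    for (i in rownames(L)) {
      if (i %in% names(config$ordinal_specs)) {
        df[[i]] <- ordinalize(meas[, i], config$ordinal_specs[[i]])
        types[i] <- "ordinal"
      } else {
        df[[i]] <- meas[, i]
        types[i] <- "continuous"
      }
    }
    attr(df, "meta") <- data.frame(
      measure = rownames(L),
      role = unname(config$measure_roles[rownames(L)]),
      type = unname(types), row.names = NULL, stringsAsFactors = FALSE)
    attr(df, "factors") <- eta
    class(df) <- c("cohort", "data.frame")
    if (any(config$missing_rates > 0))
      df <- apply_missingness(df, config$missing_rates,
                              seed = child_seed(config$seed, "missing"))
    df
  })
}

#' Measure metadata of a cohort table
#' @param cohort a cohort data frame from [generate_cohort()].
#' @return Data frame with columns `measure`, `role`, `type`.
#' @export
cohort_meta <- function(cohort) attr(cohort, "meta")

#' Mask measures completely at random
#'
#' @param cohort a cohort data frame.
#' @param missing_rates named per-measure fractions in `[0, 1)`.
#' @param seed RNG seed.
#' @return The cohort with the requested fractions set missing.
#' @export
apply_missingness <- function(cohort, missing_rates, seed = 1) {
  if (any(missing_rates < 0 | missing_rates >= 1))
    stop("missing rates must lie in [0, 1)")
  meta <- attr(cohort, "meta")
  with_seed(seed, {
    for (m in names(missing_rates)) {
      r <- missing_rates[[m]]
      if (r == 0) next
      if (!m %in% names(cohort)) stop("unknown measure: ", m)
      mask <- runif(nrow(cohort)) < r
      cohort[[m]][mask] <- NA
    }
  })
  attr(cohort, "meta") <- meta
  cohort
}

#' Write a cohort table and its metadata sidecar
#'
#' @param cohort a cohort data frame.
#' @param path output TSV path; metadata is written next to it as
#'   `<path>.meta.yaml`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- attr(cohort, "meta")
  if (!is.null(meta))
    yaml::write_yaml(lapply(split(meta, meta$measure), function(r)
      list(role = r$role, type = r$type)), paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Default ordinal category probabilities for the preschool musicality items
#'
#' Category counts of the three age-5 musicality items (has not yet done /
#' not well / well, after reverse coding) in the reference cohort
#' descriptives: sing 89/358/5596, hum 241/511/5270, clap 403/1003/4562.
#'
#' @return Named list of length-3 probability vectors.
#' @export
preschool_ordinal_specs <- function() {
  list(sing_5y = c(89, 358, 5596) / 6043,
       hum_5y = c(241, 511, 5270) / 6022,
       clap_5y = c(403, 1003, 4562) / 5968)
}

#' Configuration mirroring the reference three-factor study conditions
#'
#' The generating loadings and factor correlations are those of
#' [stage3_model()]; preschool items are ordinal with the published category
#' frequencies; missingness approximates the published per-measure Ns.
#'
#' @param n_individuals cohort size (default 5873, the reference model N).
#' @param seed RNG seed.
#' @param pgs_paths optional named standardised PGS paths per factor.
#' @param ordinal logical; generate the preschool items as 3-category
#'   ordinal measures (default) or keep all measures continuous.
#' @return A [sim_config()].
#' @export
stage3_sim_config <- function(n_individuals = 5873, seed = 1,
                              pgs_paths = NULL, ordinal = TRUE) {
  m <- stage3_model()
  sim_config(
    n_individuals = n_individuals, seed = seed,
    loading_matrix = m$loadings, factor_correlations = m$factor_cor,
    ordinal_specs = if (ordinal) preschool_ordinal_specs() else list(),
    pgs_paths = pgs_paths)
}
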