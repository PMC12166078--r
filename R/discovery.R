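#' Estimate the number of factors by the Kaiser rule
#'
#' Eigendecomposes a phenotype correlation matrix and counts eigenvalues
#' strictly greater than 1. When the scree is flat (all eigenvalues within
#' tolerance of each other) no component dominates; the count is returned
#' as computed (0 for an identity matrix) with a warning.
#'
#' @param R correlation matrix.
#' @return Integer count, with the eigenvalues attached as attribute
#'   `"eigenvalues"` for scree inspection.
#' @export
estimate_n_factors <- function(R) {
  ev <- check_psd(R, "correlation matrix")
  if (max(ev) - min(ev) < 1e-8)
    warning("flat scree: all eigenvalues equal; Kaiser rule is uninformative")
  structure(sum(ev > 1), eigenvalues = ev)
}

#' Split a cohort into two matched halves
#'
#' Within each stratum defined by the stratifiers (by default sex crossed
#' with the per-measure observed/missing signature; strata rarer than
#' `min_stratum` pooled), individuals are shuffled and assigned
#' alternately, so half sizes differ by at most one per stratum and the
#' stratifier distributions are balanced.
#'
#' @param cohort cohort data frame.
#' @param measures measure columns whose missingness signature stratifies
#'   the split (defaults to all measures in the metadata).
#' @param sex_col sex column name (set `NULL` to drop sex stratification).
#' @param min_stratum strata with fewer members are pooled.
#' @param seed RNG seed.
#' @return List `list(a, b)` of disjoint, exhaustive cohort halves.
#' @export
split_half <- function(cohort, measures = NULL, sex_col = "sex",
                       min_stratum = 4, seed = 1) {
  if (nrow(cohort) < 4) stop("need at least 4 individuals to split")
  if (is.null(measures)) {
    meta <- attr(cohort, "meta")
    measures <- if (!is.null(meta)) meta$measure else
      setdiff(names(cohort), c("individual_id", "sex", "age", paste0("PC", 1:10)))
  }
  if (!is.null(sex_col) && !sex_col %in% names(cohort))
    stop("stratifier column absent: ", sex_col)
  sig <- apply(is.na(cohort[, measures, drop = FALSE]), 1, function(r)
    paste(as.integer(r), collapse = ""))
  strat <- if (is.null(sex_col)) sig else paste(cohort[[sex_col]], sig, sep = "|")
  tab <- table(strat)
  strat[strat %in% names(tab)[tab < min_stratum]] <- "(pooled)"
  assign <- integer(nrow(cohort))
  with_seed(seed, {
    for (s in unique(strat)) {
      idx <- sample(which(strat == s))
      assign[idx] <- rep_len(c(1L, 2L), length(idx))
    }
  })
  meta <- attr(cohort, "meta")
  a <- cohort[assign == 1L, , drop = FALSE]
  b <- cohort[assign == 2L, , drop = FALSE]
  attr(a, "meta") <- attr(b, "meta") <- meta
  list(a = a, b = b)
}

# quartimin criterion and gradient for oblique gradient-projection rotation
vgQ_quartimin <- function(L) {
  L2 <- L^2
  k <- ncol(L)
  M <- matrix(1, k, k) - diag(k)
  list(f = sum(L2 * (L2 %*% M)) / 4, Gq = L * (L2 %*% M))
}

# Oblique gradient-projection rotation (quartimin = oblimin with gamma 0).
oblimin_rotate <- function(A, eps = 1e-6, maxit = 1000) {
  k <- ncol(A)
  if (k < 2) return(list(loadings = A, Phi = diag(k)))
  Tmat <- diag(k)
  al <- 1
  L <- A %*% t(solve(Tmat))
  Vg <- vgQ_quartimin(L)
  f <- Vg$f
  G <- -t(t(L) %*% Vg$Gq %*% solve(Tmat))
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < eps) break
    al <- 2 * al
    for (i in 0:20) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      L <- A %*% t(solve(Tt))
      Vgt <- vgQ_quartimin(L)
      if (Vgt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    f <- Vgt$f
    G <- -t(t(L) %*% Vgt$Gq %*% solve(Tt))
  }
  dimnames(L) <- dimnames(A)
  list(loadings = L, Phi = t(Tmat) %*% Tmat)
}

#' Two-block exploratory factor analysis with cross-block factor correlations
#'
#' Extracts an unrestricted ML factor solution separately within the
#' predictor block and the outcome block ([stats::factanal()]), rotates each
#' (varimax, or oblimin via gradient projection), and estimates the
#' correlations between factors of different blocks from Thomson
#' regression-score coefficients applied to the joint correlation matrix.
#'
#' @param data data frame of the block measures (complete cases used).
#' @param predictor_block,outcome_block column names of the two blocks.
#' @param k_predictor_factors,k_outcome_factors factors per block.
#' @param rotation `"varimax"` or `"oblimin"`.
#' @return List: `loadings` (named list per block, rows in input order),
#'   `Phi` (within-block factor correlations), `between_cor` (cross-block
#'   factor correlation matrix), `rotation`, `n`.
#' @export
efa_two_block <- function(data, predictor_block, outcome_block,
                          k_predictor_factors, k_outcome_factors,
                          rotation = c("varimax", "oblimin")) {
  rotation <- match.arg(rotation)
  stopifnot(k_predictor_factors >= 1, k_outcome_factors >= 1)
  all_m <- c(predictor_block, outcome_block)
  d <- data[stats::complete.cases(data[, all_m, drop = FALSE]), all_m, drop = FALSE]
  n <- nrow(d)
  R <- stats::cor(d)
  max_k <- function(p) floor((2 * p + 1 - sqrt(8 * p + 1)) / 2)
  if (k_predictor_factors > max_k(length(predictor_block)))
    stop("k_predictor_factors exceeds the identification limit for ",
         length(predictor_block), " measures")
  if (k_outcome_factors > max_k(length(outcome_block)))
    stop("k_outcome_factors exceeds the identification limit for ",
         length(outcome_block), " measures")
  one_block <- function(cols, k, tag) {
    fa <- stats::factanal(covmat = R[cols, cols], factors = k, n.obs = n,
                          rotation = "none")
    L <- matrix(fa$loadings, length(cols), k,
                dimnames = list(cols, paste0(tag, seq_len(k))))
    if (k == 1) return(list(loadings = L, Phi = diag(1)))
    if (rotation == "varimax") {
      r <- stats::varimax(L)
      list(loadings = matrix(r$loadings, length(cols), k, dimnames = dimnames(L)),
           Phi = diag(k))
    } else {
      r <- oblimin_rotate(L)
      list(loadings = r$loadings, Phi = r$Phi)
    }
  }
  pb <- one_block(predictor_block, k_predictor_factors, "P")
  ob <- one_block(outcome_block, k_outcome_factors, "O")
  # Thomson regression-score coefficients, then cross-block score correlations
  score_coef <- function(cols, blk) {
    solve(R[cols, cols]) %*% blk$loadings %*% blk$Phi
  }
  Ca <- score_coef(predictor_block, pb)
  Cb <- score_coef(outcome_block, ob)
  Vab <- t(Ca) %*% R[predictor_block, outcome_block] %*% Cb
  Va <- t(Ca) %*% R[predictor_block, predictor_block] %*% Ca
  Vb <- t(Cb) %*% R[outcome_block, outcome_block] %*% Cb
  between <- Vab / sqrt(tcrossprod(diag(Va), diag(Vb)))
  dimnames(between) <- list(colnames(pb$loadings), colnames(ob$loadings))
  list(loadings = list(predictor = pb$loadings, outcome = ob$loadings),
       Phi = list(predictor = pb$Phi, outcome = ob$Phi),
       between_cor = between, rotation = rotation, n = n)
}

#' Turn rotated EFA loadings into a confirmatory specification
#'
#' Frees a loading wherever its rotated absolute value strictly exceeds the
#' retention threshold (default `|lambda| > 0.1`, i.e. at least 1% of the
#' phenotypic variance) and fixes it to zero otherwise; factors are
#' variance-standardised and all factor correlations free. Measures with no
#' retained loading are dropped with a warning.
#'
#' @param efa result of [efa_two_block()], or a plain loading matrix.
#' @param retain_threshold retention cut on `|lambda|` (strict inequality).
#' @return A [cfa_spec()] over the retained measures.
#' @export
build_cfa_spec <- function(efa, retain_threshold = 0.1) {
  L <- if (is.list(efa) && !is.null(efa$loadings) && is.list(efa$loadings)) {
    lp <- efa$loadings$predictor; lo <- efa$loadings$outcome
    B <- matrix(0, nrow(lp) + nrow(lo), ncol(lp) + ncol(lo),
                dimnames = list(c(rownames(lp), rownames(lo)),
                                c(colnames(lp), colnames(lo))))
    B[rownames(lp), colnames(lp)] <- lp
    B[rownames(lo), colnames(lo)] <- lo
    B
  } else as.matrix(efa)
  if (any(!is.finite(L))) stop("loadings must be finite")
  pattern <- abs(L) > retain_threshold
  dropped <- rownames(L)[rowSums(pattern) == 0]
  if (length(dropped) == nrow(L)) stop("empty model: no loading retained")
  if (length(dropped))
    warning("measures with no retained loading dropped: ",
            paste(dropped, collapse = ", "))
  keep <- setdiff(rownames(L), dropped)
  Lr <- L[keep, , drop = FALSE]
  Lr[abs(Lr) <= retain_threshold] <- 0
  empty_f <- colSums(Lr != 0) == 0
  cfa_spec(Lr[, !empty_f, drop = FALSE])
}

#' Confirm a discovered structure on holdout data and refit on the full sample
#'
#' Fits each candidate specification (one per rotation, when they differ) on
#' the holdout half, selects the best by lowest RMSEA (ties by higher CFI),
#' then refits the chosen model on the full sample, optionally with
#' nonparametric bootstrap standard errors, and builds an interpretation
#' table flagging meaningful standardised loadings and factor correlations
#' (`|value| > 0.3`, strict).
#'
#' @param specs named list of candidate [fm_spec()]s (e.g. varimax/oblimin).
#' @param holdout cohort half used for confirmation.
#' @param full full cohort for the final refit.
#' @param B_boot bootstrap replicates for the final SEs (0 disables).
#' @param seed RNG seed.
#' @return List: `selected` (name), `holdout_fit`, `full_fit`,
#'   `interpretation` (standardised table with `meaningful` flag),
#'   `bootstrap` (or `NULL`).
#' @export
confirm_and_refit <- function(specs, holdout, full, B_boot = 1000, seed = 1) {
  if (inherits(specs, "fm_spec")) specs <- list(model = specs)
  fit_on <- function(spec, data, seed) {
    obs <- spec$observed
    d <- data[stats::complete.cases(data[, obs, drop = FALSE]), obs, drop = FALSE]
    fit_ml(spec, stats::cov(d), nrow(d), seed = seed)
  }
  hold <- lapply(seq_along(specs), function(i)
    tryCatch(fit_on(specs[[i]], holdout, seed + i), error = function(e) e))
  ok <- vapply(hold, function(f) inherits(f, "fm_fit") && f$converged, TRUE)
  if (!any(ok))
    stop("holdout confirmation failed: no candidate converged (",
         paste(vapply(hold[!vapply(hold, inherits, TRUE, "fm_fit")],
                      conditionMessage, ""), collapse = "; "), ")")
  rmsea <- vapply(hold, function(f)
    if (inherits(f, "fm_fit") && f$converged) f$indices["RMSEA"] else Inf, 0)
  cfi <- vapply(hold, function(f)
    if (inherits(f, "fm_fit") && f$converged) f$indices["CFI"] else -Inf, 0)
  best <- order(rmsea, -cfi)[1]
  spec <- specs[[best]]
  full_fit <- fit_on(spec, full, seed)
  boot <- NULL
  if (B_boot >= 2)
    boot <- bootstrap_se(full, spec, B = B_boot, seed = child_seed(seed, "boot"))
  std <- standardize(full_fit)
  structural <- grepl("=~|~~", std$parameter) &
    !grepl("^(.+)~~\\1$", std$parameter)
  interp <- std[structural, , drop = FALSE]
  interp$meaningful <- abs(interp$est_std) > 0.3
  if (!is.null(boot)) {
    m <- match(interp$parameter, names(boot$se))
    interp$se_boot <- boot$se[m]
  }
  list(selected = names(specs)[best] %||% as.character(best),
       holdout_fit = hold[[best]], full_fit = full_fit,
       interpretation = interp, bootstrap = boot)
}

# Residualise measures on covariates (complete cases across all measures,
# listwise) and scale to unit variance; the standard preprocessing before
# covariance-structure modelling of covariate-adjusted scores.
prepare_sem_data <- function(cohort, measures, covariates = c("sex", "age", paste0("PC", 1:10))) {
  covariates <- intersect(covariates, names(cohort))
  d <- cohort[stats::complete.cases(cohort[, c(measures, covariates), drop = FALSE]),
              c(measures, covariates), drop = FALSE]
  out <- d[, measures, drop = FALSE]
  if (length(covariates)) {
    X <- stats::model.matrix(~., data = d[, covariates, drop = FALSE])
    for (m in measures)
      out[[m]] <- stats::lm.fit(X, as.numeric(d[[m]]))$residuals
  }
  for (m in measures) out[[m]] <- as.numeric(scale(out[[m]]))
  out
}

#' Data-driven latent-structure discovery pipeline
#'
#' Runs the full recipe: per-block Kaiser factor-count estimation on the
#' covariate-residualised correlation matrix, matched split-half, two-block
#' EFA in half A under both rotations, loading retention into candidate
#' confirmatory specifications, confirmation on half B, and a final
#' full-sample refit.
#'
#' @param cohort cohort data frame with measure metadata (see
#'   [generate_cohort()]); composite measures flagged in the metadata are
#'   excluded up front.
#' @param predictors,outcomes measure names (defaults from metadata roles).
#' @param covariates covariate columns residualised out of every measure.
#' @param retain_threshold EFA loading retention cut.
#' @param B_boot bootstrap replicates for the final refit (0 disables).
#' @param seed RNG seed.
#' @return List: `n_factors` (per block and overall), `split` sizes, `efa`
#'   (both rotations), `confirmation` (see [confirm_and_refit()]).
#' @export
discover_structure <- function(cohort, predictors = NULL, outcomes = NULL,
                               covariates = c("sex", "age", paste0("PC", 1:10)),
                               retain_threshold = 0.1, B_boot = 0, seed = 1) {
  meta <- attr(cohort, "meta")
  if (is.null(predictors))
    predictors <- meta$measure[meta$role == "predictor"]
  if (is.null(outcomes))
    outcomes <- meta$measure[meta$role == "outcome"]
  measures <- c(predictors, outcomes)
  resid_all <- prepare_sem_data(cohort, measures, covariates)
  kp <- estimate_n_factors(stats::cor(resid_all[, predictors, drop = FALSE]))
  ko <- estimate_n_factors(stats::cor(resid_all[, outcomes, drop = FALSE]))
  koverall <- estimate_n_factors(stats::cor(resid_all))
  halves <- split_half(cohort, measures = measures, seed = seed)
  prep_a <- prepare_sem_data(halves$a, measures, covariates)
  prep_b <- prepare_sem_data(halves$b, measures, covariates)
  efas <- lapply(c(varimax = "varimax", oblimin = "oblimin"), function(rot)
    efa_two_block(prep_a, predictors, outcomes, kp, ko, rotation = rot))
  specs <- lapply(efas, build_cfa_spec, retain_threshold = retain_threshold)
  conf <- confirm_and_refit(specs, prep_b, resid_all, B_boot = B_boot,
                            seed = seed)
  list(n_factors = list(predictor = as.integer(kp), outcome = as.integer(ko),
                        overall = as.integer(koverall),
                        total = as.integer(kp) + as.integer(ko)),
       split = c(a = nrow(halves$a), b = nrow(halves$b)),
       efa = efas, specs = specs, confirmation = conf)
}
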