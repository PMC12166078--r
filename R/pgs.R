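#' Harmonise two GWAS-side tables on SNP identity and allele coding
#'
#' Intersects on `snp_id`; where the effect/other alleles of `b` are swapped
#' relative to `a`, flips the sign of `b`'s effect column (and reflects its
#' allele frequency, when present); removes strand-ambiguous SNPs (A/T and
#' C/G pairs) and SNPs whose allele pairs cannot be reconciled. Counts of
#' every removal class are attached as the `"harmonize_log"` attribute.
#'
#' @param a,b summary-statistics or weight-table data frames with columns
#'   `snp_id`, `effect_allele`, `other_allele` and an effect column
#'   (`beta` or `weight`).
#' @return List `list(a, b)` of aligned tables on the common SNP set.
#' @export
harmonize <- function(a, b) {
  eff_col <- function(d) if ("beta" %in% names(d)) "beta" else "weight"
  common <- intersect(a$snp_id, b$snp_id)
  if (!length(common)) stop("no shared SNPs between the two tables")
  a <- a[match(common, a$snp_id), , drop = FALSE]
  b <- b[match(common, b$snp_id), , drop = FALSE]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  ambiguous <- a$effect_allele == comp[a$other_allele]
  same <- a$effect_allele == b$effect_allele & a$other_allele == b$other_allele
  swapped <- a$effect_allele == b$other_allele & a$other_allele == b$effect_allele
  keep <- !ambiguous & (same | swapped)
  log <- c(shared = length(common), ambiguous_removed = sum(ambiguous),
           unresolvable_removed = sum(!ambiguous & !same & !swapped),
           flipped = sum(swapped & !ambiguous))
  flip <- swapped & keep
  ec <- eff_col(b)
  b[[ec]][flip] <- -b[[ec]][flip]
  if ("freq" %in% names(b)) b$freq[flip] <- 1 - b$freq[flip]
  tmp <- b$effect_allele[flip]
  b$effect_allele[flip] <- b$other_allele[flip]
  b$other_allele[flip] <- tmp
  a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  if (!nrow(a)) stop("no SNPs left after allele harmonisation")
  rownames(a) <- rownames(b) <- NULL
  out <- list(a = a, b = b)
  attr(out, "harmonize_log") <- log
  out
}

#' Compute polygenic scores from dosages and a weight table
#'
#' `score_i = sum_j dosage_ij * weight_j` over the SNPs shared between the
#' genotype panel and the weight table, with allele codings aligned first
#' (a weight whose effect allele is the panel's other allele contributes
#' with dosage `2 - d`). Missing dosages are imputed to `2 * MAF`.
#'
#' @param genotypes dosage matrix (individuals x SNPs) with a `snp_info`
#'   attribute carrying `snp_id`, `effect_allele`, `maf`.
#' @param weights weight-table data frame.
#' @param standardise Z-standardise the score across individuals (default).
#' @return Numeric score vector; the number of SNPs used is attached as
#'   attribute `"n_snps_used"`.
#' @export
score_pgs <- function(genotypes, weights, standardise = TRUE) {
  info <- attr(genotypes, "snp_info")
  if (is.null(info)) stop("genotype matrix lacks snp_info attribute")
  common <- intersect(info$snp_id, weights$snp_id)
  if (!length(common)) stop("no overlap between genotypes and weights")
  G <- genotypes[, common, drop = FALSE]
  info <- info[match(common, info$snp_id), ]
  w <- weights[match(common, weights$snp_id), ]
  # align weight to the panel's effect allele
  flip <- !is.na(info$other_allele) & w$effect_allele == info$other_allele &
    w$other_allele == info$effect_allele
  beta <- w$weight
  beta[flip] <- -beta[flip]
  unresolved <- w$effect_allele != info$effect_allele & !flip
  if (any(unresolved)) {
    G <- G[, !unresolved, drop = FALSE]
    beta <- beta[!unresolved]
    info <- info[!unresolved, ]
    if (!length(beta)) stop("no resolvable SNP overlap")
  }
  if (anyNA(G)) {
    for (j in seq_len(ncol(G))) {
      miss <- is.na(G[, j])
      if (any(miss)) G[miss, j] <- 2 * info$maf[j]
    }
  }
  raw <- as.numeric(G %*% beta)
  out <- raw
  if (standardise) {
    s <- stats::sd(raw)
    if (!is.finite(s) || s < 1e-12)
      stop("zero-variance raw score; cannot Z-standardise")
    out <- (raw - mean(raw)) / s
  }
  attr(out, "n_snps_used") <- length(beta)
  out
}

#' GWAS-by-subtraction: remove a confounder trait's genetic signal
#'
#' Fits the two-trait Cholesky decomposition `S_genetic = L L'` with the
#' confounder trait first: the confounder loads a first latent genetic
#' factor (`lambda11`), the focal trait loads both that factor
#' (`lambda21`) and its own residual factor (`lambda22`). Per SNP the
#' latent effects are solved from
#' `b1 = beta_conf / lambda11` and
#' `b2 = (beta_trait - lambda21 * b1) / lambda22`, and the subtracted
#' (confounder-free) effect is `lambda22 * b2`. Standard errors are
#' propagated by the delta method assuming independent input errors.
#'
#' @param S_genetic 2x2 positive-definite genetic covariance, confounder
#'   trait first (e.g. from LD-score regression, supplied as input).
#' @param ss_confounder,ss_trait harmonised summary-statistics data frames.
#' @return Summary statistics of the subtracted trait (same layout as the
#'   focal trait; `n` left as the focal trait's, see [effective_n()]), with
#'   the Cholesky loadings attached as attribute `"cholesky"`.
#' @export
subtract_cholesky <- function(S_genetic, ss_confounder, ss_trait) {
  S_genetic <- as.matrix(S_genetic)
  check_psd(S_genetic, "S_genetic")
  h <- harmonize(ss_confounder, ss_trait)
  conf <- h$a; trait <- h$b
  L <- t(chol(S_genetic))        # lower-triangular
  l11 <- L[1, 1]; l21 <- L[2, 1]; l22 <- L[2, 2]
  if (abs(l22) < 1e-10)
    stop("focal trait fully explained by the confounder (lambda22 ~ 0)")
  b1 <- conf$beta / l11
  b2 <- (trait$beta - l21 * b1) / l22
  ratio <- l21 / l11
  beta_sub <- trait$beta - ratio * conf$beta   # = l22 * b2, computed stably
  se_sub <- sqrt(trait$se^2 + ratio^2 * conf$se^2)
  out <- trait
  out$beta <- beta_sub
  out$se <- se_sub
  attr(out, "cholesky") <- c(lambda11 = l11, lambda21 = l21, lambda22 = l22)
  attr(out, "latent") <- data.frame(b_latent1 = b1, b_latent2 = b2)
  attr(out, "harmonize_log") <- attr(h, "harmonize_log")
  out
}

#' Effective GWAS sample size from standardised-trait standard errors
#'
#' For a standardised trait, `var(beta_j) ~ 1 / (2 p_j (1 - p_j) N)`, so
#' each SNP yields `N_j = 1 / (2 p_j (1 - p_j) se_j^2)`. Returns the mean
#' over SNPs inside the allele-frequency window (default MAF 10-40%), where
#' the approximation is most stable.
#'
#' @param ss summary-statistics data frame with `freq` and `se`.
#' @param maf_window inclusive minor-allele-frequency window.
#' @return Estimated effective sample size (numeric scalar).
#' @export
effective_n <- function(ss, maf_window = c(0.1, 0.4)) {
  maf <- pmin(ss$freq, 1 - ss$freq)
  inside <- maf >= maf_window[1] & maf <= maf_window[2]
  if (!any(inside)) stop("no SNPs inside the MAF window")
  p <- ss$freq[inside]
  mean(1 / (2 * p * (1 - p) * ss$se[inside]^2))
}
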