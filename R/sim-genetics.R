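# Non-strand-ambiguous allele pairs (no A/T or C/G), matching the QC state
# of panels that survive harmonisation.
draw_allele_pairs <- function(n_snps) {
  alleles <- c("A", "C", "G", "T")
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  a1 <- sample(alleles, n_snps, replace = TRUE)
  a2 <- vapply(a1, function(a)
    sample(setdiff(alleles, c(a, comp[[a]])), 1), "")
  list(a1 = a1, a2 = unname(a2))
}

#' Generate a genotype panel, weight table and calibrated polygenic score
#'
#' Simulates `n_snps` independent biallelic SNPs with dosages
#' `Binomial(2, maf)`, draws per-SNP weights, and returns the Z-standardised
#' weighted dosage sum together with the standardised path coefficient
#' `sqrt(target_incremental_r2)` that makes the score explain the requested
#' fraction of a unit-variance factor when fed to [generate_cohort()] via
#' `pgs_paths`.
#'
#' @param n number of individuals.
#' @param n_snps number of SNPs (must be >= 1).
#' @param target_incremental_r2 variance fraction in `[0, 1)` the score
#'   should explain of a designated factor.
#' @param seed RNG seed.
#' @param maf_range minor-allele-frequency range for the simulated panel.
#' @return List: `genotypes` (n x n_snps dosage matrix with SNP metadata
#'   attributes), `weights` (a weight table data frame, PRS-CS-style
#'   columns), `pgs` (Z-standardised score), `path`
#'   (`sqrt(target_incremental_r2)`), `maf`.
#' @export
generate_genotypes_pgs <- function(n, n_snps, target_incremental_r2 = 0.01,
                                   seed = 1, maf_range = c(0.05, 0.5)) {
  if (n_snps < 1) stop("n_snps must be >= 1; no score is definable otherwise")
  if (target_incremental_r2 < 0 || target_incremental_r2 >= 1)
    stop("target_incremental_r2 must lie in [0, 1)")
  with_seed(seed, {
    maf <- runif(n_snps, maf_range[1], maf_range[2])
    G <- vapply(seq_len(n_snps), function(j) rbinom(n, 2, maf[j]),
                numeric(n))
    snp <- sprintf("rs%06d", seq_len(n_snps))
    colnames(G) <- snp
    pair <- draw_allele_pairs(n_snps)
    a1 <- pair$a1; a2 <- pair$a2
    w <- rnorm(n_snps)
    raw <- as.numeric(G %*% w)
    if (stats::sd(raw) < 1e-12)
      stop("degenerate score: weighted dosage sum has zero variance")
    pgs <- as.numeric(scale(raw))
    weights <- data.frame(chr = 1L, snp_id = snp, bp = seq_len(n_snps) * 1000L,
                          effect_allele = a1, other_allele = a2,
                          weight = w, stringsAsFactors = FALSE)
    attr(G, "snp_info") <- data.frame(snp_id = snp, effect_allele = a1,
                                      other_allele = a2, maf = maf,
                                      stringsAsFactors = FALSE)
    list(genotypes = G, weights = weights, pgs = pgs,
         path = sqrt(target_incremental_r2), maf = maf)
  })
}

#' Generate a correlated pair of GWAS summary-statistic tables
#'
#' Per-SNP standardised effect pairs are drawn from a bivariate normal with
#' covariance `genetic_cov` (confounder trait first), so the across-SNP
#' covariance of the two beta columns matches the requested genetic
#' covariance; estimation noise is added with per-SNP standard error
#' `1/sqrt(2 p (1-p) N)` for a standardised trait.
#'
#' @param n_snps number of SNPs.
#' @param genetic_cov 2x2 positive semi-definite genetic covariance; row 1 is
#'   the confounder trait (e.g. educational attainment), row 2 the focal
#'   trait (e.g. rhythmicity).
#' @param n per-trait GWAS sample sizes (length 2, recycled).
#' @param seed RNG seed.
#' @param maf_range effect-allele-frequency range.
#' @return List of two summary-statistics data frames
#'   (`confounder`, `trait`), each with columns
#'   `snp_id, effect_allele, other_allele, freq, beta, se, n`, plus the
#'   noise-free latent effects as attribute `"true_beta"`.
#' @export
generate_sumstats_pair <- function(n_snps, genetic_cov, n = c(6e5, 6e5),
                                   seed = 1, maf_range = c(0.05, 0.5)) {
  genetic_cov <- as.matrix(genetic_cov)
  check_psd(genetic_cov, "genetic_cov")
  n <- rep(n, length.out = 2)
  with_seed(seed, {
    maf <- runif(n_snps, maf_range[1], maf_range[2])
    snp <- sprintf("rs%06d", seq_len(n_snps))
    pair <- draw_allele_pairs(n_snps)
    a1 <- pair$a1; a2 <- pair$a2
    B <- rmvn(n_snps, genetic_cov)
    mk <- function(k) {
      se <- 1 / sqrt(2 * maf * (1 - maf) * n[k])
      beta <- B[, k] + rnorm(n_snps, 0, se)
      out <- data.frame(snp_id = snp, effect_allele = a1, other_allele = a2,
                        freq = maf, beta = beta, se = se, n = n[k],
                        stringsAsFactors = FALSE)
      attr(out, "true_beta") <- B[, k]
      out
    }
    list(confounder = mk(1), trait = mk(2))
  })
}

#' Write summary statistics as a 7-column TSV (SNP A1 A2 FRQ BETA SE N)
#' @param ss summary-statistics data frame.
#' @param path output path.
#' @export
write_sumstats <- function(ss, path) {
  out <- data.frame(SNP = ss$snp_id, A1 = ss$effect_allele,
                    A2 = ss$other_allele, FRQ = ss$freq, BETA = ss$beta,
                    SE = ss$se, N = ss$n)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read summary statistics from a SNP/A1/A2/FRQ/BETA/SE/N TSV
#' @param path input path.
#' @param col_map optional named vector remapping nonstandard column names.
#' @export
read_sumstats <- function(path, col_map = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  std <- c(SNP = "snp_id", A1 = "effect_allele", A2 = "other_allele",
           FRQ = "freq", BETA = "beta", SE = "se", N = "n")
  if (!is.null(col_map)) names(d)[match(col_map, names(d))] <- names(col_map)
  missing <- setdiff(names(std), names(d))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  out <- d[, names(std)]
  names(out) <- std
  if (any(out$freq <= 0 | out$freq >= 1)) stop("FRQ must lie in (0, 1)")
  if (any(out$se <= 0)) stop("SE must be positive")
  out
}

#' Write a weight table as PRS-CS-style 6-column TSV (CHR SNP BP A1 A2 BETA)
#' @param weights weight-table data frame.
#' @param path output path.
#' @export
write_weights <- function(weights, path) {
  out <- data.frame(CHR = weights$chr, SNP = weights$snp_id,
                    BP = weights$bp, A1 = weights$effect_allele,
                    A2 = weights$other_allele, BETA = weights$weight)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PRS-CS-style weight table (CHR SNP BP A1 A2 BETA)
#' @param path input path.
#' @export
read_weights <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("CHR", "SNP", "BP", "A1", "A2", "BETA"), names(d))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  data.frame(chr = d$CHR, snp_id = d$SNP, bp = d$BP, effect_allele = d$A1,
             other_allele = d$A2, weight = d$BETA, stringsAsFactors = FALSE)
}

#' Write genotype dosages in PLINK .raw-style layout
#'
#' Header `FID IID PAT MAT SEX PHENOTYPE <SNP>_<A1> ...`, one row per
#' individual, dosages in 0-2.
#'
#' @param genotypes dosage matrix from [generate_genotypes_pgs()].
#' @param path output path.
#' @export
write_genotypes_raw <- function(genotypes, path) {
  info <- attr(genotypes, "snp_info")
  if (is.null(info)) stop("genotype matrix lacks snp_info attribute")
  hdr <- paste0(info$snp_id, "_", info$effect_allele)
  out <- data.frame(FID = seq_len(nrow(genotypes)),
                    IID = seq_len(nrow(genotypes)),
                    PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = -9L)
  out <- cbind(out, as.data.frame(genotypes))
  names(out)[-(1:6)] <- hdr
  utils::write.table(out, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotype dosages from a PLINK .raw-style file
#' @param path input path.
#' @return Dosage matrix with a `snp_info` attribute recovered from the
#'   `<SNP>_<A1>` headers (other allele unknown, set `NA`).
#' @export
read_genotypes_raw <- function(path) {
  d <- utils::read.delim(path, sep = " ", stringsAsFactors = FALSE,
                         check.names = FALSE)
  snp_cols <- setdiff(names(d), c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
  G <- as.matrix(d[, snp_cols, drop = FALSE])
  ids <- sub("_[ACGT]$", "", snp_cols)
  a1 <- sub("^.*_", "", snp_cols)
  colnames(G) <- ids
  attr(G, "snp_info") <- data.frame(snp_id = ids, effect_allele = a1,
                                    other_allele = NA_character_,
                                    maf = colMeans(G, na.rm = TRUE) / 2,
                                    stringsAsFactors = FALSE)
  G
}
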