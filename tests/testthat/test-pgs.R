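test_that("harmonisation aligns alleles, flips swapped effects, drops ambiguous", {
  fx <- three_snp_pair()
  # identical tables pass through unchanged (minus the ambiguous A/T SNP)
  h0 <- harmonize(fx$a, fx$a)
  expect_equal(h0$a$beta, h0$b$beta)
  log0 <- attr(h0, "harmonize_log")
  expect_equal(unname(log0["ambiguous_removed"]), 1)

  h <- harmonize(fx$a, fx$b)
  expect_equal(nrow(h$a), 2)                    # rs3 (A/T) removed
  expect_false("rs3" %in% h$a$snp_id)
  # rs2 had swapped alleles: sign flipped back into a's frame
  expect_equal(h$b$beta[h$b$snp_id == "rs2"], -0.25)
  expect_equal(h$b$beta[h$b$snp_id == "rs1"], 0.1)
  log <- attr(h, "harmonize_log")
  expect_equal(unname(log["flipped"]), 1)

  b2 <- fx$b
  b2$snp_id <- c("x1", "x2", "x3")
  expect_error(harmonize(fx$a, b2), "no shared SNPs")
})

test_that("polygenic scoring matches hand arithmetic and the flip invariance", {
  G <- matrix(c(0, 1, 2), 1, 3)
  info <- data.frame(snp_id = c("s1", "s2", "s3"),
                     effect_allele = c("A", "C", "G"),
                     other_allele = c("G", "T", "A"),
                     maf = c(0.2, 0.3, 0.4), stringsAsFactors = FALSE)
  colnames(G) <- info$snp_id
  attr(G, "snp_info") <- info
  w <- data.frame(snp_id = info$snp_id, effect_allele = info$effect_allele,
                  other_allele = info$other_allele,
                  weight = c(0.1, -0.2, 0.3), stringsAsFactors = FALSE)
  raw <- score_pgs(G, w, standardise = FALSE)
  expect_equal(as.numeric(raw), 0 * 0.1 + 1 * -0.2 + 2 * 0.3)

  # simultaneous allele-coding flip leaves standardised scores unchanged
  g <- generate_genotypes_pgs(400, 60, 0.01, seed = 6)
  s1 <- score_pgs(g$genotypes, g$weights)
  Gf <- 2 - g$genotypes
  inf <- attr(g$genotypes, "snp_info")
  attr(Gf, "snp_info") <- data.frame(snp_id = inf$snp_id,
                                     effect_allele = inf$other_allele,
                                     other_allele = inf$effect_allele,
                                     maf = 1 - inf$maf,
                                     stringsAsFactors = FALSE)
  s2 <- score_pgs(Gf, g$weights)
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-10)

  expect_equal(mean(s1), 0, tolerance = 1e-12)
  expect_equal(sd(s1), 1, tolerance = 1e-12)

  # zero weights give a degenerate score
  w0 <- g$weights; w0$weight <- 0
  expect_error(score_pgs(g$genotypes, w0), "zero-variance")

  # missing dosages are imputed to 2*MAF
  Gm <- g$genotypes
  Gm[1, 1] <- NA
  sm <- score_pgs(Gm, g$weights, standardise = FALSE)
  s0 <- score_pgs(g$genotypes, g$weights, standardise = FALSE)
  delta <- (2 * inf$maf[1] - g$genotypes[1, 1]) *
    g$weights$weight[g$weights$snp_id == inf$snp_id[1]]
  expect_equal(unname(sm[1] - s0[1]), unname(delta), tolerance = 1e-10)
})

test_that("GWAS-by-subtraction satisfies its algebraic identities", {
  G <- matrix(c(0.12, 0.02, 0.02, 0.05), 2, 2)
  ss <- generate_sumstats_pair(2000, G, seed = 8)
  sub <- subtract_cholesky(G, ss$confounder, ss$trait)
  ch <- attr(sub, "cholesky")
  lat <- attr(sub, "latent")
  # round trip: lambda21 b1 + lambda22 b2 reconstructs the focal betas
  recon <- ch["lambda21"] * lat$b_latent1 + ch["lambda22"] * lat$b_latent2
  expect_equal(recon, ss$trait$beta, tolerance = 1e-12, ignore_attr = TRUE)

  # diagonal genetic covariance: subtracted equals original
  sub0 <- subtract_cholesky(diag(c(0.12, 0.05)), ss$confounder, ss$trait)
  expect_equal(sub0$beta, ss$trait$beta, tolerance = 1e-12)

  # full confounding: beta_trait proportional to beta_conf -> all zero
  conf <- ss$confounder
  trait <- ss$trait
  trait$beta <- (ch["lambda21"] / ch["lambda11"]) * conf$beta
  subf <- subtract_cholesky(G, conf, trait)
  expect_lt(max(abs(subf$beta)), 1e-12)

  # subtracted effects uncorrelated with the confounder's
  expect_lt(abs(cor(sub$beta, ss$confounder$beta)), 3 / sqrt(2000))

  expect_error(subtract_cholesky(matrix(c(0.1, 0.2, 0.2, 0.1), 2, 2),
                                 ss$confounder, ss$trait),
               "positive semi-definite")
})

test_that("effective sample size is recovered from standardised-trait SEs", {
  ss <- generate_sumstats_pair(5000, diag(c(0.1, 0.1)), n = c(10000, 10000),
                               seed = 9)$trait
  est <- effective_n(ss)
  expect_equal(est, 10000, tolerance = 0.05)
  ss2 <- ss
  ss2$se <- ss$se * sqrt(2)
  expect_equal(effective_n(ss2), est / 2, tolerance = 1e-10)

  one <- data.frame(snp_id = "s", effect_allele = "A", other_allele = "G",
                    freq = 0.5, beta = 0, se = 0.01, n = NA)
  expect_equal(effective_n(one, maf_window = c(0.4, 0.5)), 20000)
  expect_error(effective_n(one, maf_window = c(0.01, 0.02)), "MAF window")
})

test_that("summary statistics and weights survive a disk round trip", {
  g <- generate_genotypes_pgs(50, 20, 0.01, seed = 2)
  ss <- generate_sumstats_pair(20, diag(c(0.1, 0.05)), seed = 2)
  td <- withr::local_tempdir()
  write_weights(g$weights, file.path(td, "w.tsv"))
  w2 <- read_weights(file.path(td, "w.tsv"))
  expect_equal(w2$weight, g$weights$weight)
  write_sumstats(ss$trait, file.path(td, "ss.tsv"))
  s2 <- read_sumstats(file.path(td, "ss.tsv"))
  expect_equal(s2$beta, ss$trait$beta)
  write_genotypes_raw(g$genotypes, file.path(td, "g.raw"))
  G2 <- read_genotypes_raw(file.path(td, "g.raw"))
  expect_equal(unname(G2[, 1]), unname(g$genotypes[, 1]))
  sc <- score_pgs(G2, g$weights)
  expect_equal(as.numeric(sc), as.numeric(score_pgs(g$genotypes, g$weights)),
               tolerance = 1e-10)
})
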