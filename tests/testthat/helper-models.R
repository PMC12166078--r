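# Shared fixtures: small factor models and simulated datasets built in code.

# Two-factor, four-indicator model with simple structure.
two_factor_spec <- function() {
  L <- matrix(c(0.8, 0.7, 0, 0,
                0, 0, 0.6, 0.5), 4, 2,
              dimnames = list(paste0("y", 1:4), c("f1", "f2")))
  spec <- cfa_spec(L)
  params <- c("f1=~y1" = 0.8, "f1=~y2" = 0.7, "f2=~y3" = 0.6, "f2=~y4" = 0.5,
              "f1~~f2" = 0.3,
              "y1~~y1" = 1 - 0.64, "y2~~y2" = 1 - 0.49,
              "y3~~y3" = 1 - 0.36, "y4~~y4" = 1 - 0.25)
  list(spec = spec, params = params,
       sigma = implied_covariance(spec, params))
}

simulate_mvn <- function(n, sigma, seed = 1) {
  set.seed(seed)
  X <- as.data.frame(musicom:::rmvn(n, sigma))
  names(X) <- colnames(sigma)
  X
}

# Hand-built 3-SNP harmonisation fixture: one matching SNP, one with swapped
# alleles, one strand-ambiguous (A/T).
three_snp_pair <- function() {
  a <- data.frame(snp_id = c("rs1", "rs2", "rs3"),
                  effect_allele = c("A", "C", "A"),
                  other_allele = c("G", "T", "T"),
                  freq = c(0.2, 0.3, 0.4),
                  beta = c(0.1, 0.2, 0.3), se = c(0.01, 0.01, 0.01),
                  n = 1000, stringsAsFactors = FALSE)
  b <- a
  b$effect_allele <- c("A", "T", "A")
  b$other_allele <- c("G", "C", "T")
  b$beta <- c(0.1, 0.25, 0.3)
  list(a = a, b = b)
}
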