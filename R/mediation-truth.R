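#' Generating parameterisation for the PGS-embedded mediation model
#'
#' Builds the mediation specification over the reference three-factor
#' structure together with a fully determined generating parameter vector:
#' the score path onto the musicality factor (`a`), the score paths onto
#' the outcome factors (`b`), the direct musicality-to-outcome paths
#' (`c`), disturbance variances solved so every factor has unit variance,
#' and the outcome-disturbance covariance solved so the implied
#' cognition-speech correlation matches `cor_outcomes`. Defaults follow
#' the published Stage-3 decomposition: shared effect `a b` of 0.0054 and
#' total `a b + c` of 0.4554 for the speech factor, and 0.001 / 0.32 for
#' the cognition factor.
#'
#' @param a standardised score-to-musicality path.
#' @param b named score-to-outcome paths (`cognition`, `speech`).
#' @param c_direct named direct musicality-to-outcome paths.
#' @param cor_outcomes target implied cognition-speech correlation.
#' @param pgs_name score column name.
#' @return List: `spec` (mediation [fm_spec()]), `params` (generating
#'   vector), `sigma` (implied covariance over the 10 observed variables),
#'   `shared`/`total` (the generating products).
#' @export
stage3_mediation_truth <- function(a = 0.09,
                                   b = c(cognition = 0.0111, speech = 0.06),
                                   c_direct = c(cognition = 0.319, speech = 0.45),
                                   cor_outcomes = 0.56,
                                   pgs_name = "pgs_rhythmicity") {
  m <- stage3_model()
  spec <- build_mediation_spec(m$spec, pgs_name, "musicality",
                               c("cognition", "speech"))
  params <- m$params
  # measurement part unchanged; structural part re-expressed with paths
  params <- params[setdiff(names(params),
                           c("musicality~~cognition", "musicality~~speech",
                             "cognition~~speech"))]
  params[paste0(pgs_name, "~~", pgs_name)] <- 1
  params["a"] <- a
  var_d <- c(musicality = 1 - a^2)
  for (f in c("cognition", "speech")) {
    params[paste0("b_", f)] <- b[f]
    params[paste0("c_", f)] <- c_direct[f]
    var_d[f] <- 1 - (b[f]^2 + c_direct[f]^2 + 2 * a * b[f] * c_direct[f])
    if (var_d[f] <= 0) stop("generating paths imply nonpositive disturbance variance for ", f)
  }
  # outcome-disturbance covariance matching the target factor correlation
  bc <- b["cognition"]; bs <- b["speech"]
  cc <- c_direct["cognition"]; cs <- c_direct["speech"]
  d_cov <- cor_outcomes - (bc * bs + cc * cs + a * (bc * cs + bs * cc))
  # factor (disturbance) variances/covariance live on the latent S entries
  spec$S$value["musicality", "musicality"] <- var_d["musicality"]
  spec$S$value["cognition", "cognition"] <- var_d["cognition"]
  spec$S$value["speech", "speech"] <- var_d["speech"]
  params["cognition~~speech"] <- d_cov
  sigma <- implied_covariance(spec, params)
  list(spec = spec, params = params, sigma = sigma,
       shared = a * b, total = a * b + c_direct)
}
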