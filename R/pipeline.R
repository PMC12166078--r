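#' Default pipeline configuration
#'
#' All analysis constants live here and are overridable: retention and
#' meaningfulness thresholds, Bonferroni inputs, the spectral-decomposition
#' method, bootstrap replicates, and the simulation block defining the
#' synthetic study conditions (reference three-factor structure, published
#' ordinal category frequencies, PGS effect sizes in the reported
#' incremental-R-squared range).
#'
#' @param n_individuals synthetic cohort size.
#' @param seed master seed governing every stage.
#' @return Nested configuration list.
#' @export
default_config <- function(n_individuals = 2000, seed = 1) {
  list(
    seed = seed,
    stages = c("simulate", "screen", "discover", "pgs_score", "pgs_assoc",
               "subtract", "mediate", "report"),
    simulate = list(n_individuals = n_individuals, n_snps = 500,
                    target_incremental_r2 = 0.008,
                    pgs_factor = "musicality", ordinal = TRUE,
                    genetic_cov = matrix(c(0.12, 0.02, 0.02, 0.05), 2, 2),
                    n_sumstats_snps = 5000),
    screen = list(alpha = 0.05, min_max_r2 = 0.01),
    discover = list(retain_threshold = 0.1, meaningful_threshold = 0.3,
                    B_boot = 0),
    meff = list(method = "li_ji", alpha = 0.05),
    mediate = list(se_method = "delta"),
    covariates = c("sex", "age", paste0("PC", 1:10))
  )
}

#' Run the three-stage pipeline end to end
#'
#' Executes the requested stages in dependency order on a synthetic cohort
#' (or inputs named in the config), writing inter-stage artefacts, a
#' manifest of seeds, thresholds, per-stage sample sizes and every
#' exclusion decision into the run directory.
#'
#' Stages: `simulate` (cohort + genotypes + score + summary-statistic
#' pair), `screen` (Stage-1 incremental-R-squared screen and predictor
#' filtering), `discover` (split-half EFA to CFA), `pgs_score` (recompute
#' the score from the weight table), `pgs_assoc` (Stage-2 ordinal and
#' continuous score associations with the spectral-decomposition
#' threshold), `subtract` (GWAS-by-subtraction of the confounder trait),
#' `mediate` (Stage-3 decomposition), `report`.
#'
#' @param config configuration list (see [default_config()]) or path to a
#'   YAML file with the same layout.
#' @param outdir run directory (created if absent).
#' @return The run directory path, invisibly; artefacts live inside it.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("musicom_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  if (!is.matrix(cfg$simulate$genetic_cov))
    cfg$simulate$genetic_cov <- matrix(unlist(cfg$simulate$genetic_cov), 2, 2)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- cfg$stages
  seed <- cfg$seed
  manifest <- list(seed = seed, stages = stages,
                   thresholds = list(retain = cfg$discover$retain_threshold,
                                     meaningful = cfg$discover$meaningful_threshold,
                                     screen_alpha = cfg$screen$alpha,
                                     meff_method = cfg$meff$method),
                   exclusions = list(), n = list())
  state <- new.env(parent = emptyenv())

  need <- function(stage, dep, artefact) {
    if (!exists(artefact, envir = state))
      stop(sprintf("stage '%s' requires artefact '%s' from stage '%s'",
                   stage, artefact, dep), call. = FALSE)
    get(artefact, envir = state)
  }

  if ("simulate" %in% stages) {
    sim <- cfg$simulate
    gen <- generate_genotypes_pgs(sim$n_individuals, sim$n_snps,
                                  sim$target_incremental_r2,
                                  seed = child_seed(seed, "geno"))
    paths <- setNames(gen$path, sim$pgs_factor)
    sc <- stage3_sim_config(sim$n_individuals, seed = child_seed(seed, "cohort"),
                            pgs_paths = paths, ordinal = sim$ordinal)
    cohort <- generate_cohort(sc, pgs = gen$pgs)
    cohort$pgs_rhythmicity <- gen$pgs
    ss <- generate_sumstats_pair(sim$n_sumstats_snps, sim$genetic_cov,
                                 seed = child_seed(seed, "sumstats"))
    assign("cohort", cohort, envir = state)
    assign("genetics", gen, envir = state)
    assign("sumstats", ss, envir = state)
    write_cohort(cohort, file.path(outdir, "cohort.tsv"))
    write_weights(gen$weights, file.path(outdir, "weights.tsv"))
    write_sumstats(ss$confounder, file.path(outdir, "sumstats_confounder.tsv"))
    write_sumstats(ss$trait, file.path(outdir, "sumstats_trait.tsv"))
    manifest$n$cohort <- nrow(cohort)
  }

  meta_of <- function(cohort) attr(cohort, "meta")

  if ("screen" %in% stages) {
    cohort <- need("screen", "simulate", "cohort")
    meta <- meta_of(cohort)
    predictors <- meta$measure[meta$role == "predictor"]
    outcomes <- meta$measure[meta$role == "outcome"]
    tab <- screen_associations(cohort, predictors, outcomes,
                               covariates = cfg$covariates,
                               alpha = cfg$screen$alpha)
    kept <- filter_predictors(tab, cfg$screen$min_max_r2)
    manifest$exclusions$predictors_dropped <- setdiff(predictors, kept)
    manifest$n$screen_pairs <- nrow(tab)
    utils::write.table(tab, file.path(outdir, "screen.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    assign("screen", tab, envir = state)
    assign("kept_predictors", kept, envir = state)
  }

  if ("discover" %in% stages) {
    cohort <- need("discover", "simulate", "cohort")
    disc <- discover_structure(cohort, covariates = cfg$covariates,
                               retain_threshold = cfg$discover$retain_threshold,
                               B_boot = cfg$discover$B_boot,
                               seed = child_seed(seed, "discover"))
    assign("discovery", disc, envir = state)
    manifest$n$split <- as.list(disc$split)
    manifest$n$factors <- disc$n_factors
    spec <- disc$confirmation$full_fit$spec
    yaml::write_yaml(spec_to_list(spec), file.path(outdir, "cfa_spec.yaml"))
    utils::write.table(disc$confirmation$interpretation,
                       file.path(outdir, "interpretation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    fit <- disc$confirmation$full_fit
    utils::write.table(standardize(fit), file.path(outdir, "report_cfa.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    append_fit_index(outdir, "cfa_full_sample", fit)
    append_fit_index(outdir, "cfa_holdout", disc$confirmation$holdout_fit)
  }

  if ("pgs_score" %in% stages) {
    gen <- need("pgs_score", "simulate", "genetics")
    cohort <- need("pgs_score", "simulate", "cohort")
    score <- score_pgs(gen$genotypes, gen$weights)
    cohort$pgs_rhythmicity <- score
    assign("cohort", cohort, envir = state)
    manifest$n$pgs_snps <- attr(score, "n_snps_used")
  }

  if ("pgs_assoc" %in% stages) {
    cohort <- need("pgs_assoc", "simulate", "cohort")
    meta <- meta_of(cohort)
    rows <- list()
    for (m in meta$measure) {
      rows[[m]] <- if (meta$type[meta$measure == m] == "ordinal")
        incremental_nagelkerke(cohort, m, "pgs_rhythmicity", cfg$covariates)
      else {
        r <- incremental_r2(cohort, m, "pgs_rhythmicity", cfg$covariates)
        r$beta <- NA_real_; r$se <- NA_real_
        r[, c("predictor", "outcome", "n", "beta", "se", "incremental_r2",
              "statistic", "p")]
      }
    }
    assoc <- do.call(rbind, rows)
    meas <- meta$measure
    resid <- prepare_sem_data(cohort, meas, cfg$covariates)
    meff <- meff_spectral(stats::cor(resid), method = cfg$meff$method)
    assoc$pass_meff <- assoc$p < bonferroni(meff$meff, cfg$meff$alpha)
    manifest$n$meff <- meff$meff
    manifest$thresholds$meff_p <- bonferroni(meff$meff, cfg$meff$alpha)
    utils::write.table(assoc, file.path(outdir, "pgs_assoc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    assign("pgs_assoc", assoc, envir = state)
  }

  if ("subtract" %in% stages) {
    ss <- need("subtract", "simulate", "sumstats")
    sub <- subtract_cholesky(cfg$simulate$genetic_cov, ss$confounder, ss$trait)
    write_sumstats(sub, file.path(outdir, "sumstats_subtracted.tsv"))
    manifest$n$subtract_snps <- nrow(sub)
    manifest$exclusions$snps_removed <-
      as.list(attr(sub, "harmonize_log")[c("ambiguous_removed",
                                           "unresolvable_removed")])
    assign("subtracted", sub, envir = state)
  }

  if ("mediate" %in% stages) {
    cohort <- need("mediate", "simulate", "cohort")
    if (!exists("discovery", envir = state))
      stop("stage 'mediate' requires artefact 'discovery' from stage 'discover'",
           call. = FALSE)
    disc <- get("discovery", envir = state)
    meta <- meta_of(cohort)
    spec <- disc$confirmation$full_fit$spec
    pred_f <- spec$latent[1]
    med_spec <- build_mediation_spec(spec, "pgs_rhythmicity", pred_f)
    d <- prepare_sem_data(cohort, spec$observed, cfg$covariates)
    keep <- stats::complete.cases(cohort[, c(spec$observed,
                                             cfg$covariates), drop = FALSE])
    d$pgs_rhythmicity <- as.numeric(scale(cohort$pgs_rhythmicity[keep]))
    med <- estimate_effects(med_spec, d, se_method = cfg$mediate$se_method,
                            seed = child_seed(seed, "mediate"))
    assign("mediation", med, envir = state)
    manifest$n$mediation <- med$n
    utils::write.table(med$effects, file.path(outdir, "report_mediation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    append_fit_index(outdir, "mediation", med$fit)
  }

  manifest$completed <- intersect(stages, c("simulate", "screen", "discover",
                                            "pgs_score", "pgs_assoc",
                                            "subtract", "mediate"))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  if ("report" %in% stages) write_report(outdir)
  invisible(outdir)
}

# One fit-index row per fitted model, accumulated across stages; rewritten
# from scratch on a fresh run (the file is truncated by the first append of
# a run via the `reset` flag held in an option-free sentinel).
append_fit_index <- function(outdir, model, fit) {
  path <- file.path(outdir, "fit_indices.tsv")
  row <- data.frame(model = model, n = fit$n, T = fit$T, df = fit$df,
                    CFI = fit$indices[["CFI"]], TLI = fit$indices[["TLI"]],
                    RMSEA = fit$indices[["RMSEA"]],
                    SRMR = fit$indices[["SRMR"]])
  old <- if (file.exists(path)) {
    prev <- utils::read.delim(path)
    prev[prev$model != model, , drop = FALSE]
  } else NULL
  out <- rbind(old, row)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

spec_to_list <- function(spec) {
  lam <- list()
  for (f in spec$latent)
    lam[[f]] <- spec$observed[spec$A$free[spec$observed, f]]
  list(observed = spec$observed, latent = spec$latent, loadings = lam,
       defined = as.list(spec$defined))
}

#' Write the report tables of a pipeline run
#'
#' Derives the reporting units of the analysis purely from the artefacts in
#' the run directory: the Stage-1 screen table, the Stage-2 score
#' association table, the CFA table (standardised loadings and correlations
#' with SEs), the mediation table (a, b, c, shared, total with SEs and
#' p-values) and one fit-index row per fitted model, bundled into
#' `report.json`. Because it reads only the on-disk artefacts, regeneration
#' is idempotent.
#'
#' @param outdir run directory of [run_pipeline()].
#' @return `outdir`, invisibly.
#' @export
write_report <- function(outdir) {
  if (!dir.exists(outdir) || !length(list.files(outdir)))
    stop("empty run directory: ", outdir)
  grab <- function(f) {
    p <- file.path(outdir, f)
    if (file.exists(p)) utils::read.delim(p) else NULL
  }
  report <- list()
  report$screen <- grab("screen.tsv")
  report$pgs_assoc <- grab("pgs_assoc.tsv")
  report$cfa <- grab("report_cfa.tsv")
  report$mediation <- grab("report_mediation.tsv")
  report$fit_indices <- grab("fit_indices.tsv")
  report <- report[!vapply(report, is.null, TRUE)]
  if (!length(report)) stop("no completed stage artefacts in ", outdir)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, dataframe = "rows", na = "null")
  invisible(outdir)
}
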