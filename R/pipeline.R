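## End-to-end pipeline: generate (or load) a population and a set of
## rejection experiments, quantify mimicry fidelity, fit the rejection
## models, and run the parasitism simulations with the monomorphic
## counterfactual and fecundity projection.

#' Default pipeline configuration
#'
#' Nested list of parameter blocks for each stage. Any subset can be
#' overridden via `run_pipeline(config = list(...))` or a YAML file with
#' the same structure; unknown keys are rejected.
#'
#' @return nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    inputs = list(phenotype_csv = NULL, experiments_csv = NULL),
    synthdata = list(n_females_host = 166, n_females_parasite = 28,
                     eggs_per_female = 3, n_experiments = 114,
                     candidates = 5, true_coefficients = c(-1.8, 1.6)),
    fidelity = list(dfa_traits = c("dispersion", "total_energy",
                                   "n_features", "catch_mw", "catch_dbl"),
                    collinearity_threshold = 0.7,
                    outlier_filter = FALSE),
    rejection = list(distance_mode = "z"),
    simulate = list(n_iterations = 1000, mode = "bernoulli"),
    fecundity = list(eggs_per_year = 20, nest_survival = 0.202,
                     lifespan_years = 8, alt_success_rate = 0.27,
                     rejection_rate = NULL)  # NULL = use simulated rate
  )
}

merge_config <- function(base, override, path = "config") {
  for (nm in names(override)) {
    stop_if(!nm %in% names(base), "unknown %s key: %s", path, nm)
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]],
                                 paste(path, nm, sep = "$"))
    else base[[nm]] <- override[[nm]]
  }
  base
}

## hash of the analysis-relevant configuration (output location excluded,
## so reruns into different directories remain byte-identical)
config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(cfg, f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: (1) load or generate the phenotype table and
#' experiment table; (2) fidelity: per-trait repeatability across females,
#' host-vs-parasite rank tests, collinearity screen and jack-knifed
#' discriminant analysis with its exact test; (3) rejection: composite and
#' distance standardization fits on the pooled population,
#' trait-difference model (model 1) and distance model (model 2), AIC /
#' LRT comparison, VIF and variance partitioning for model 1; (4)
#' simulation: Monte-Carlo parasitism rejection rate, monomorphic
#' counterfactual, predicted fate of the experimental pairs, and the
#' fecundity projection. Every stage failure is re-raised with a stage
#' tag. If `out_dir` is set, writes `traits.csv`, `experiments.csv`,
#' `fidelity.csv`, `models.json`, `simulation.json` and `summary.txt`,
#' each carrying the config hash and seed.
#'
#' @param config nested list overriding [default_pipeline_config()], or a
#'   path to a YAML file with the same structure.
#' @return list with `table`, `experiments`, `fidelity`, `rejection`,
#'   `simulation`, `config`, `config_hash`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    stop_if(!file.exists(config), "no such config file: %s", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_pipeline_config(), config)
  hash <- config_hash(cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  ## stage: data
  dat <- stage("data", {
    if (!is.null(cfg$inputs$phenotype_csv)) {
      tab <- read_phenotype_table(cfg$inputs$phenotype_csv)
    } else {
      pc <- population_config(
        n_females_host = cfg$synthdata$n_females_host,
        n_females_parasite = cfg$synthdata$n_females_parasite,
        eggs_per_female = cfg$synthdata$eggs_per_female,
        seed = cfg$seed)
      tab <- generate_population(pc)
    }
    if (!is.null(cfg$inputs$experiments_csv)) {
      exps <- read.csv(cfg$inputs$experiments_csv, stringsAsFactors = FALSE)
    } else {
      exps <- generate_experiments(
        tab, true_coefficients = cfg$synthdata$true_coefficients,
        n_experiments = cfg$synthdata$n_experiments,
        seed = cfg$seed + 1L, candidates = cfg$synthdata$candidates)
    }
    list(table = tab, experiments = exps)
  })
  tab <- dat$table

  ## stage: fidelity
  fid <- stage("fidelity", {
    traits <- c("shape_ratio", "prop_pattern", "total_energy", "sd_energy",
                "n_features", "catch_uv", "catch_sw", "catch_mw",
                "catch_lw", "catch_dbl")
    icc_tab <- do.call(rbind, lapply(traits, function(tr) {
      r <- icc(tab[[tr]], tab$female_id)
      data.frame(trait = tr, icc = r$icc, F = r$F, p = r$p)
    }))
    wil_tab <- do.call(rbind, lapply(traits, function(tr) {
      w <- rank_sum_test(tab[[tr]][tab$species == "host"],
                         tab[[tr]][tab$species == "parasite"])
      data.frame(trait = tr, W = w$W, p = w$p)
    }))
    dfa_traits <- collinearity_screen(
      impute_immaculate(tab)[, cfg$fidelity$dfa_traits],
      cfg$fidelity$collinearity_threshold)
    one <- impute_immaculate(tab[!duplicated(tab$female_id), ])
    dfa <- lda_jackknife(one[, dfa_traits], one$species,
                         outlier_filter = cfg$fidelity$outlier_filter)
    ft <- confusion_exact_test(dfa$confusion)
    list(icc = icc_tab, wilcoxon = wil_tab, dfa_traits = dfa_traits,
         dfa = dfa, fisher = ft)
  })

  ## stage: rejection
  rej <- stage("rejection", {
    std <- fit_distance_standardization(tab, mode = cfg$rejection$distance_mode)
    comps <- fit_composites(tab)
    records <- assemble_experiment_records(dat$experiments, tab)
    d1 <- build_predictors(records, "traits", composites = comps)
    d2 <- build_predictors(records, "distance", std = std)
    m1 <- fit_rejection_glm(d1, "model 1: trait differences")
    m2 <- fit_rejection_glm(d2, "model 2: pattern distance")
    list(std = std, composites = comps, records = records,
         model1 = m1, model2 = m2,
         comparison = compare_models(m1, m2),
         partition_model1 = partition_variance(d1))
  })

  ## stage: simulate
  sim <- stage("simulate", {
    hosts <- tab[tab$species == "host", ]
    paras <- tab[tab$species == "parasite", ]
    s <- simulate_parasitism(hosts, paras, rej$model2, rej$std,
                             n_iterations = cfg$simulate$n_iterations,
                             mode = cfg$simulate$mode,
                             seed = cfg$seed + 2L)
    mono <- monomorphic_counterfactual(hosts, paras, rej$model2, rej$std)
    pred_pairs <- simulate_experiment_set(
      data.frame(distance = pattern_distance_rows(
        strip_prefix(rej$records, "host_"),
        strip_prefix(rej$records, "exp_"), rej$std)), rej$model2)
    fec_rate <- cfg$fecundity$rejection_rate %||% s$rejection_rate
    fec <- fecundity_projection(
      eggs_per_year = cfg$fecundity$eggs_per_year,
      rejection_rate = fec_rate,
      nest_survival = cfg$fecundity$nest_survival,
      lifespan_years = cfg$fecundity$lifespan_years,
      alt_success_rate = cfg$fecundity$alt_success_rate)
    list(parasitism = s, counterfactual = mono,
         experiment_pairs = pred_pairs, fecundity = fec)
  })

  out <- list(table = tab, experiments = dat$experiments, fidelity = fid,
              rejection = rej, simulation = sim, config = cfg,
              config_hash = hash)
  if (!is.null(cfg$out_dir)) stage("write", write_pipeline_outputs(out))
  out
}

write_pipeline_outputs <- function(res) {
  dir.create(res$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(res$config$out_dir, f)
  meta <- list(config_hash = res$config_hash, seed = res$config$seed)
  write_phenotype_table(res$table, p("traits.csv"))
  write.csv(res$experiments, p("experiments.csv"), row.names = FALSE)
  fid <- merge(res$fidelity$icc, res$fidelity$wilcoxon, by = "trait",
               suffixes = c("_icc", "_wilcoxon"))
  write.csv(fid, p("fidelity.csv"), row.names = FALSE)
  jsonlite::write_json(c(meta, list(
    dfa_traits = res$fidelity$dfa_traits,
    dfa_rates = as.list(res$fidelity$dfa$correct_rates),
    fisher = res$fidelity$fisher,
    model1 = fit_summary(res$rejection$model1),
    model2 = fit_summary(res$rejection$model2),
    comparison = res$rejection$comparison,
    partition_model1 = as.list(res$rejection$partition_model1))),
    p("models.json"), auto_unbox = TRUE, digits = NA, na = "null")
  s <- res$simulation
  jsonlite::write_json(c(meta, list(
    rejection_rate = s$parasitism$rejection_rate,
    ci = s$parasitism$ci, mode = s$parasitism$mode,
    n_iterations = s$parasitism$n_iterations,
    counterfactual = s$counterfactual,
    expected_accepted_pairs = s$experiment_pairs$expected_accepted,
    fecundity = s$fecundity[names(s$fecundity) != "display"])),
    p("simulation.json"), auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(c(
    sprintf("config %s seed %d", res$config_hash, res$config$seed),
    sprintf("eggs: %d (%d host females, %d parasite females)",
            nrow(res$table), length(unique(res$table$female_id[
              res$table$species == "host"])),
            length(unique(res$table$female_id[
              res$table$species == "parasite"]))),
    sprintf("DFA correct rates: %s",
            paste(sprintf("%s %.1f%%", names(res$fidelity$dfa$correct_rates),
                          100 * res$fidelity$dfa$correct_rates),
                  collapse = ", ")),
    sprintf("model 2 vs model 1 delta AIC: %.2f",
            res$rejection$comparison$delta_aic),
    sprintf("simulated rejection rate: %.1f%%",
            100 * s$parasitism$rejection_rate),
    sprintf("monomorphic counterfactual: distance %.3f, p(reject) %.1f%%",
            s$counterfactual$centroid_distance,
            100 * s$counterfactual$p_reject),
    sprintf("fecundity: %.3g accepted eggs/yr, %.2g fledglings/yr, %.2g lifetime",
            s$fecundity$accepted_eggs_per_year,
            s$fecundity$fledglings_per_year,
            s$fecundity$lifetime_fledglings)),
    p("summary.txt"))
  invisible(res$config$out_dir)
}

fit_summary <- function(fit) {
  list(coefficients = as.list(fit$coefficients), se = as.list(fit$se),
       aic = fit$aic, logLik = fit$logLik, adj_r2 = fit$adj_r2,
       mcfadden_r2 = fit$mcfadden_r2,
       vif = if (is.null(fit$vif)) NULL else as.list(fit$vif), n = fit$n)
}
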