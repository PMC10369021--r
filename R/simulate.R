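## Monte-Carlo parasitism simulation, the monomorphic counterfactual, and
## the fecundity projection that turns a rejection rate into expected
## reproductive output.

#' Simulate parasitism events and predict the population rejection rate
#'
#' Repeatedly samples (with replacement) one host egg and one parasite egg,
#' computes their multidimensional pattern distance, and predicts the
#' probability of rejection from a fitted distance model. In `"bernoulli"`
#' mode each event's fate is drawn from that probability and the rate is
#' the rejected fraction with a Clopper-Pearson exact binomial CI; in
#' `"expected"` mode the rate is the mean predicted probability with a
#' normal (delta-method) CI. Only one egg per female enters the sampling
#' pool by default, so females with larger clutches are not over-weighted.
#'
#' @param hosts,parasites phenotype tables (rows of one species each).
#' @param fit a distance-model [fit_rejection_glm()] (single predictor
#'   `distance`).
#' @param std the [fit_distance_standardization()] shared with the fit.
#' @param n_iterations number of simulated parasitism events (default
#'   1000).
#' @param mode `"bernoulli"` (default) or `"expected"`.
#' @param seed integer seed.
#' @param one_per_female sample at most one egg per female (default TRUE;
#'   the first egg of each female is used).
#' @param conf_level CI level (default 0.95).
#' @return object of class `simulation_result`: `rejection_rate`, `ci`,
#'   `distances`, `p_reject`, `mode`, `n_iterations`, `seed`.
#' @export
simulate_parasitism <- function(hosts, parasites, fit, std,
                                n_iterations = 1000,
                                mode = c("bernoulli", "expected"),
                                seed = 1L, one_per_female = TRUE,
                                conf_level = 0.95) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "rejection_fit"))
  stop_if(!identical(fit$predictors, "distance"),
          "simulation needs a distance-only model (predictors: %s)",
          paste(fit$predictors, collapse = ", "))
  stop_if(nrow(hosts) == 0 || nrow(parasites) == 0, "empty population table")
  if (one_per_female) {
    hosts <- hosts[!duplicated(hosts$female_id), , drop = FALSE]
    parasites <- parasites[!duplicated(parasites$female_id), , drop = FALSE]
  }
  set.seed(as.integer(seed))
  ih <- sample.int(nrow(hosts), n_iterations, replace = TRUE)
  ip <- sample.int(nrow(parasites), n_iterations, replace = TRUE)
  d <- pattern_distance_rows(hosts[ih, , drop = FALSE],
                             parasites[ip, , drop = FALSE], std)
  p <- predict_rejection(fit, data.frame(distance = d))
  if (mode == "bernoulli") {
    rejected <- rbinom(n_iterations, 1, p)
    rate <- mean(rejected)
    ci <- as.numeric(binom.test(sum(rejected), n_iterations,
                                conf.level = conf_level)$conf.int)
  } else {
    rate <- mean(p)
    se <- sd(p) / sqrt(n_iterations)
    zq <- qnorm(1 - (1 - conf_level) / 2)
    ci <- pmin(pmax(c(rate - zq * se, rate + zq * se), 0), 1)
  }
  structure(list(rejection_rate = rate, ci = ci, distances = d,
                 p_reject = p, mode = mode, n_iterations = n_iterations,
                 seed = as.integer(seed)),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> rejection %.1f%% [%.1f%%, %.1f%%] (%s mode, %d iterations)\n",
              100 * x$rejection_rate, 100 * x$ci[1], 100 * x$ci[2],
              x$mode, x$n_iterations))
  invisible(x)
}

#' Predicted fate of a set of real experimental pairs
#'
#' Applies a fitted rejection model to actual host / experimental-egg
#' pairs and reports the expected number of acceptances
#' (`sum(1 - p_i)`) and the count of pairs predicted accepted under a 0.5
#' threshold. Used to ask how many of a set of experimental eggs would
#' have been accepted had they been paired at random.
#'
#' @param pairs data frame holding the fit's predictor columns (e.g. a
#'   `distance` column for a distance model).
#' @param fit a [fit_rejection_glm()].
#' @return list with `expected_accepted`, `threshold_accepted`, `p_reject`.
#' @export
simulate_experiment_set <- function(pairs, fit) {
  stop_if(nrow(pairs) == 0, "no experimental pairs")
  p <- predict_rejection(fit, pairs)
  list(expected_accepted = sum(1 - p),
       threshold_accepted = sum(p < 0.5),
       p_reject = p)
}

#' Monomorphic-population counterfactual
#'
#' Collapses each species to its centroid in standardized 5-D pattern
#' space (the phenotype both species would have if they were monomorphic),
#' and reports the distance between the two centroids and the
#' model-predicted probability that such a parasite egg would be rejected.
#' Comparing this with the polymorphic simulation isolates the defensive
#' contribution of signature diversity: a small centroid distance with a
#' large polymorphic rejection rate means rejection is driven by
#' between-female variation, not species-level differences.
#'
#' @inheritParams simulate_parasitism
#' @return list with `centroid_distance`, `p_reject`.
#' @export
monomorphic_counterfactual <- function(hosts, parasites, fit, std,
                                       one_per_female = TRUE) {
  stop_if(nrow(hosts) == 0 || nrow(parasites) == 0, "empty population table")
  stopifnot(inherits(fit, "rejection_fit"))
  if (one_per_female) {
    hosts <- hosts[!duplicated(hosts$female_id), , drop = FALSE]
    parasites <- parasites[!duplicated(parasites$female_id), , drop = FALSE]
  }
  ch <- colMeans(z_traits(hosts, std))
  cp <- colMeans(z_traits(parasites, std))
  d <- sqrt(sum((ch - cp)^2))
  list(centroid_distance = d,
       p_reject = predict_rejection(fit, data.frame(distance = d)))
}

#' Fecundity projection under a given rejection rate
#'
#' Bookkeeping arithmetic linking the simulated rejection rate to expected
#' reproductive output of a parasite female:
#' `accepted = eggs_per_year * (1 - rejection_rate)`,
#' `fledglings = accepted * nest_survival`,
#' `lifetime = fledglings * lifespan_years`, and for comparison the output
#' of a parasite with per-egg success `alt_success_rate` (e.g. the common
#' cuckoo's 27% laying-to-fledging success). `display` rounds to 2
#' significant figures.
#'
#' @param eggs_per_year eggs laid per season (default 20).
#' @param rejection_rate probability a laid egg is rejected (default 0.937).
#' @param nest_survival probability an accepted egg's nest survives to
#'   fledging (default 0.202).
#' @param lifespan_years reproductive lifespan (default 8, the
#'   conservative end of an 8-9 year estimate).
#' @param alt_success_rate laying-to-fledging success of the comparison
#'   species (default 0.27).
#' @return list with `accepted_eggs_per_year`, `fledglings_per_year`,
#'   `lifetime_fledglings`, `alt_fledglings_per_year` and a `display`
#'   sub-list of 2-significant-figure values.
#' @export
#' @examples
#' fecundity_projection()$display
fecundity_projection <- function(eggs_per_year = 20, rejection_rate = 0.937,
                                 nest_survival = 0.202, lifespan_years = 8,
                                 alt_success_rate = 0.27) {
  stop_if(rejection_rate < 0 || rejection_rate > 1 ||
            nest_survival < 0 || nest_survival > 1 ||
            alt_success_rate < 0 || alt_success_rate > 1,
          "rates must be in [0, 1]")
  stop_if(eggs_per_year < 0 || lifespan_years < 0, "counts must be >= 0")
  accepted <- eggs_per_year * (1 - rejection_rate)
  fledglings <- accepted * nest_survival
  lifetime <- fledglings * lifespan_years
  alt <- eggs_per_year * alt_success_rate
  out <- list(accepted_eggs_per_year = accepted,
              fledglings_per_year = fledglings,
              lifetime_fledglings = lifetime,
              alt_fledglings_per_year = alt)
  out$display <- lapply(out, signif, digits = 2)
  out
}
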