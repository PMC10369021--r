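## Synthetic egg-rejection experiments: conspecific host eggs swapped into
## host clutches, with acceptance/rejection drawn from a logistic function
## of multidimensional pattern distance.

#' Generate synthetic egg-rejection experiments
#'
#' Each experiment pairs a host clutch with a conspecific experimental egg
#' laid by a different female (a surrogate parasitic egg, mimicking natural
#' parasite laying behaviour). The outcome is Bernoulli with
#' `p(reject) = plogis(b0 + b1 * D)` where `D` is the multidimensional
#' pattern distance between the host egg and the experimental egg.
#' `candidates > 1` emulates the field protocol of giving hosts difficult
#' decisions: for each experiment that many candidate eggs are drawn and
#' the closest (smallest `D`) is used; `candidates = 1` gives random
#' pairing.
#'
#' @param table phenotype table from [generate_population()] (host rows are
#'   used; the standardization is fitted on the full pooled table).
#' @param true_coefficients `c(b0, b1)` of the generating logistic rule.
#'   The default (-1.8, 1.6) is back-solved from the two operating points
#'   of the fitted field model of rejection (probability 0.359 at distance
#'   0.75, and approximately 0.937 at the typical distance between
#'   unrelated eggs, about 3 pooled-z units).
#' @param n_experiments number of experiments (default 114).
#' @param seed integer seed (independent of the population seed).
#' @param candidates number of candidate eggs per experiment (see above).
#' @param same_female if `TRUE`, the experimental egg is another egg of the
#'   host female herself (a near-zero-distance control design).
#' @param std optional [fit_distance_standardization()]; default fitted on
#'   `table` (pooled species, z mode).
#' @return data frame with columns `experiment_id`, `host_clutch_id`,
#'   `host_egg_id`, `experimental_egg_id`, `distance`, `outcome`
#'   (0 = accepted, 1 = rejected).
#' @export
generate_experiments <- function(table, true_coefficients = c(-1.8, 1.6),
                                 n_experiments = 114, seed = 1L,
                                 candidates = 5, same_female = FALSE,
                                 std = NULL) {
  hosts <- table[table$species == "host", , drop = FALSE]
  stop_if(length(unique(hosts$female_id)) < 2,
          "need at least 2 host females to pair experiments")
  stop_if(length(true_coefficients) != 2, "true_coefficients must be c(b0, b1)")
  if (is.null(std)) std <- fit_distance_standardization(table)
  set.seed(as.integer(seed))
  females <- unique(hosts$female_id)
  host_rows <- integer(n_experiments)
  exp_rows <- integer(n_experiments)
  dists <- numeric(n_experiments)
  zh <- z_traits(hosts, std)
  for (i in seq_len(n_experiments)) {
    f <- sample(females, 1L)
    own <- which(hosts$female_id == f)
    host_rows[i] <- own[sample.int(length(own), 1L)]
    pool <- if (same_female) setdiff(own, host_rows[i]) else
      which(hosts$female_id != f)
    stop_if(length(pool) == 0, "no candidate experimental eggs available")
    cand <- pool[sample.int(length(pool), min(candidates, length(pool)))]
    dd <- sqrt(colSums((t(zh[cand, , drop = FALSE]) - zh[host_rows[i], ])^2))
    j <- which.min(dd)
    exp_rows[i] <- cand[j]
    dists[i] <- dd[j]
  }
  p <- plogis(true_coefficients[1] + true_coefficients[2] * dists)
  data.frame(
    experiment_id = sprintf("X%03d", seq_len(n_experiments)),
    host_clutch_id = hosts$clutch_id[host_rows],
    host_egg_id = hosts$egg_id[host_rows],
    experimental_egg_id = hosts$egg_id[exp_rows],
    distance = dists,
    outcome = rbinom(n_experiments, 1, p),
    stringsAsFactors = FALSE)
}
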