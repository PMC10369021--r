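# fit a distance model on synthetic experiments, reused across blocks
fit_distance_model <- function(tab, seed = 30, n = 150) {
  std <- fit_distance_standardization(tab)
  exps <- generate_experiments(tab, n_experiments = n, seed = seed)
  rec <- assemble_experiment_records(exps, tab)
  fit <- fit_rejection_glm(build_predictors(rec, "distance", std = std))
  list(fit = fit, std = std)
}

# a distance model with exactly known coefficients (b0, b1), built by
# overriding the coefficients of a fitted glm object
known_model <- function(tab, b0, b1) {
  fm <- fit_distance_model(tab)
  fm$fit$glm$coefficients[] <- c(b0, b1)
  fm$fit$coefficients[] <- c(b0, b1)
  fm
}

test_that("parasitism simulation is seeded, bounded and mode-consistent", {
  tab <- small_population(seed = 21)
  fm <- fit_distance_model(tab)
  hosts <- tab[tab$species == "host", ]
  paras <- tab[tab$species == "parasite", ]
  s1 <- simulate_parasitism(hosts, paras, fm$fit, fm$std, seed = 5)
  s2 <- simulate_parasitism(hosts, paras, fm$fit, fm$std, seed = 5)
  expect_identical(s1, s2)
  expect_true(s1$rejection_rate >= 0 && s1$rejection_rate <= 1)
  expect_true(s1$ci[1] <= s1$rejection_rate && s1$rejection_rate <= s1$ci[2])
  # expected mode equals the average of bernoulli rates across seeds
  se <- simulate_parasitism(hosts, paras, fm$fit, fm$std, seed = 5,
                            mode = "expected", n_iterations = 2000)
  bern <- vapply(1:100, function(s)
    simulate_parasitism(hosts, paras, fm$fit, fm$std, seed = s,
                        n_iterations = 200)$rejection_rate, numeric(1))
  mc_se <- sd(bern) / sqrt(length(bern))
  expect_lt(abs(mean(bern) - se$rejection_rate), 3 * mc_se + 0.02)
  # a trait-model fit is refused
  comps <- fit_composites(tab)
  exps <- generate_experiments(tab, n_experiments = 100, seed = 31)
  rec <- assemble_experiment_records(exps, tab)
  m1 <- fit_rejection_glm(build_predictors(rec, "traits", composites = comps))
  expect_error(simulate_parasitism(hosts, paras, m1, fm$std),
               "distance-only")
})

test_that("degenerate populations give the closed-form rejection rates", {
  tab <- small_population(seed = 22)
  # monomorphic identical populations: all distances zero, expected-mode
  # rate is exactly plogis(b0)
  fm <- known_model(tab, b0 = -0.7, b1 = 2)
  one <- tab[1, ]
  s <- simulate_parasitism(one, one, fm$fit, fm$std, mode = "expected",
                           n_iterations = 50, seed = 1)
  expect_equal(s$rejection_rate, plogis(-0.7), tolerance = 1e-12)
  # distances pushed far out: p -> 1
  far <- one
  far$n_features <- one$n_features + 1000
  s1 <- simulate_parasitism(one, far, fm$fit, fm$std, n_iterations = 200,
                            seed = 2)
  expect_equal(s1$rejection_rate, 1)
})

test_that("the four-pair enumeration matches the logistic oracle", {
  # hosts at the origin, one parasite at distance 0 and one at distance 2
  # (raw units), beta = (0, 1): expected rate over the four equally likely
  # pairs is (2 * 0.5 + 2 * plogis(2)) / 4 = 0.6904
  base <- small_population(seed = 23)
  fm <- known_model(base, b0 = 0, b1 = 1)
  fm$std <- raw_std()
  zero <- as.data.frame(c(list(species = "host", female_id = c("f1", "f2"),
                               egg_id = c("e1", "e2")),
                          egg_traits(0, 1, 0, 0, 0)))
  para <- zero
  para$species <- "parasite"
  para$female_id <- c("p1", "p2")
  para$n_features <- c(0, 2)
  s <- simulate_parasitism(zero, para, fm$fit, fm$std, mode = "expected",
                           n_iterations = 40000, seed = 3)
  oracle <- (2 * 0.5 + 2 * plogis(2)) / 4
  expect_equal(oracle, 0.6904, tolerance = 1e-4)
  expect_equal(s$rejection_rate, oracle, tolerance = 0.01 / oracle)
})

test_that("experiment-set prediction obeys its definitions", {
  tab <- small_population(seed = 24)
  fm <- known_model(tab, b0 = -1, b1 = 1.5)
  pairs <- data.frame(distance = c(0, 0.5, 1, 3))
  out <- simulate_experiment_set(pairs, fm$fit)
  expect_equal(out$expected_accepted, sum(1 - out$p_reject))
  expect_equal(out$threshold_accepted, sum(out$p_reject < 0.5))
  # identical eggs with b0 < 0: every pair predicted accepted
  same <- data.frame(distance = rep(0, 6))
  expect_equal(simulate_experiment_set(same, fm$fit)$threshold_accepted, 6)
  expect_error(simulate_experiment_set(pairs[0, , drop = FALSE], fm$fit),
               "no experimental pairs")
})

test_that("random pairing is predicted far less acceptable than biased pairing", {
  tab <- generate_population(population_config(seed = 25))
  std <- fit_distance_standardization(tab)
  biased <- generate_experiments(tab, n_experiments = 114, seed = 26,
                                 candidates = 5)
  random <- generate_experiments(tab, n_experiments = 114, seed = 26,
                                 candidates = 1)
  rec <- assemble_experiment_records(biased, tab)
  fit <- fit_rejection_glm(build_predictors(rec, "distance", std = std))
  acc_biased <- simulate_experiment_set(
    data.frame(distance = biased$distance), fit)$expected_accepted
  acc_random <- simulate_experiment_set(
    data.frame(distance = random$distance), fit)$expected_accepted
  expect_lt(acc_random, acc_biased)
  expect_lt(acc_random, sum(1 - biased$outcome))
})

test_that("the monomorphic counterfactual collapses to centroid arithmetic", {
  tab <- small_population(seed = 27)
  fm <- known_model(tab, b0 = -1, b1 = 2)
  hosts <- tab[tab$species == "host", ]
  mono <- monomorphic_counterfactual(hosts, hosts, fm$fit, fm$std)
  expect_equal(mono$centroid_distance, 0, tolerance = 1e-12)
  expect_equal(mono$p_reject, plogis(-1), tolerance = 1e-12)
  # two 2-egg toy populations, raw units: hand Euclidean arithmetic
  std <- raw_std()
  a <- as.data.frame(c(list(species = "host", female_id = c("f1", "f2"),
                            egg_id = c("e1", "e2")),
                       egg_traits(0, 1, 0, 0, 0)))
  a$total_energy <- c(0, 2)
  b <- a
  b$female_id <- c("p1", "p2")
  b$total_energy <- c(3, 5)
  b$n_features <- c(4, 4)
  mono2 <- monomorphic_counterfactual(a, b, fm$fit, std)
  # centroids differ by (0,0,3,0,4): distance 5
  expect_equal(mono2$centroid_distance, 5, tolerance = 1e-12)
})

test_that("signature diversity drives rejection far above the monomorphic rate", {
  tab <- generate_population(population_config(seed = 28))
  fm <- fit_distance_model(tab, seed = 29, n = 114)
  hosts <- tab[tab$species == "host", ]
  paras <- tab[tab$species == "parasite", ]
  s <- simulate_parasitism(hosts, paras, fm$fit, fm$std, seed = 30)
  mono <- monomorphic_counterfactual(hosts, paras, fm$fit, fm$std)
  expect_gt(s$rejection_rate, mono$p_reject)
  expect_lt(mono$centroid_distance, quantile(s$distances, 0.1))
})

test_that("fecundity projection reproduces its arithmetic exactly", {
  f <- fecundity_projection(eggs_per_year = 20, rejection_rate = 0.937,
                            nest_survival = 0.202, lifespan_years = 8,
                            alt_success_rate = 0.27)
  expect_equal(f$accepted_eggs_per_year, 1.26, tolerance = 1e-12)
  expect_equal(f$display$fledglings_per_year, 0.25)
  expect_equal(f$alt_fledglings_per_year, 5.4, tolerance = 1e-12)
  expect_equal(f$lifetime_fledglings, 1.26 * 0.202 * 8, tolerance = 1e-12)
  zero <- fecundity_projection(eggs_per_year = 0)
  expect_equal(unlist(zero[names(zero) != "display"]),
               c(accepted_eggs_per_year = 0, fledglings_per_year = 0,
                 lifetime_fledglings = 0, alt_fledglings_per_year = 0))
  expect_error(fecundity_projection(rejection_rate = 1.2), "rates")
})
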