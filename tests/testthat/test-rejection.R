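make_records <- function(tab, exps) assemble_experiment_records(exps, tab)

test_that("predictor construction follows the model specifications", {
  tab <- small_population(seed = 5)
  exps <- generate_experiments(tab, n_experiments = 60, seed = 6)
  rec <- make_records(tab, exps)
  std <- fit_distance_standardization(tab)
  comps <- fit_composites(tab)
  d1 <- build_predictors(rec, "traits", composites = comps)
  expect_named(d1, c("outcome", "d_pattern_coverage", "d_pc_energy",
                     "d_n_features"))
  expect_true(all(d1$d_n_features >= 0))
  expect_equal(d1$d_n_features,
               abs(rec$host_n_features - rec$exp_n_features))
  d2 <- build_predictors(rec, "distance", std = std)
  expect_equal(d2$distance,
               eggsig:::pattern_distance_rows(
                 eggsig:::strip_prefix(rec, "host_"),
                 eggsig:::strip_prefix(rec, "exp_"), std))
  # a host paired with its own egg has zero difference predictors
  self_exp <- exps[1, ]
  self_exp$experimental_egg_id <- self_exp$host_egg_id
  rec0 <- make_records(tab, self_exp)
  d10 <- build_predictors(rec0, "traits", composites = comps)
  expect_equal(unlist(d10[1, -1]), c(d_pattern_coverage = 0,
                                     d_pc_energy = 0, d_n_features = 0))
  expect_equal(build_predictors(rec0, "distance", std = std)$distance, 0)
  dcol <- build_predictors(rec, "plus_colour", std = std)
  expect_named(dcol, c("outcome", "distance", "chromatic_jnd"))
  expect_true(all(dcol$chromatic_jnd >= 0))
  dint <- build_predictors(rec, "interactions", composites = comps)
  expect_true("d_pattern_coverage:d_pc_energy" %in% names(dint))
  expect_error(build_predictors(rec, "nonsense"), "arg")
})

test_that("the binomial GLM fit reports its accounting identities", {
  tab <- small_population(seed = 7)
  exps <- generate_experiments(tab, n_experiments = 120, seed = 8)
  rec <- make_records(tab, exps)
  std <- fit_distance_standardization(tab)
  fit <- fit_rejection_glm(build_predictors(rec, "distance", std = std))
  expect_equal(fit$aic, 2 * length(fit$coefficients) - 2 * fit$logLik)
  p <- predict_rejection(fit, data.frame(distance = c(0, 1, 2, 5)))
  expect_true(all(p > 0 & p < 1))
  expect_true(all(diff(p) > 0))  # monotone in distance when slope > 0
  expect_error(fit_rejection_glm(data.frame(outcome = rep(1, 10))),
               "both outcome classes")
  # perfect separation is detected and refused
  sep <- data.frame(outcome = rep(c(0, 1), each = 20),
                    x = c(rnorm(20, -5), rnorm(20, 5)))
  expect_error(fit_rejection_glm(sep), "separation")
})

test_that("a single simulated experiment recovers its generating coefficients", {
  tab <- generate_population(population_config(seed = 17))
  exps <- generate_experiments(tab, true_coefficients = c(-2, 3),
                               n_experiments = 500, seed = 18,
                               candidates = 1)
  rec <- make_records(tab, exps)
  std <- fit_distance_standardization(tab)
  fit <- fit_rejection_glm(build_predictors(rec, "distance", std = std))
  expect_lt(abs(fit$coefficients[1] - (-2)) / fit$se[1], 2)
  expect_lt(abs(fit$coefficients[2] - 3) / fit$se[2], 2)
})

test_that("adding a pure-noise predictor costs about two AIC points", {
  set.seed(51)
  tab <- small_population(seed = 9)
  exps <- generate_experiments(tab, n_experiments = 150, seed = 10)
  rec <- make_records(tab, exps)
  std <- fit_distance_standardization(tab)
  base_data <- build_predictors(rec, "distance", std = std)
  deltas <- vapply(1:100, function(i) {
    noisy <- base_data
    noisy$noise <- rnorm(nrow(noisy))
    fit_rejection_glm(noisy)$aic - fit_rejection_glm(base_data)$aic
  }, numeric(1))
  # delta AIC = 2 - chi2_1 draw; median chi2_1 = 0.455 -> median ~ +1.5
  expect_gt(median(deltas), 0.8)
  expect_lt(median(deltas), 2)
})

test_that("model comparison reports AIC always and LRT only when nested", {
  tab <- small_population(seed = 11)
  exps <- generate_experiments(tab, n_experiments = 120, seed = 12)
  rec <- make_records(tab, exps)
  std <- fit_distance_standardization(tab)
  comps <- fit_composites(tab)
  d2 <- build_predictors(rec, "distance", std = std)
  m2 <- fit_rejection_glm(d2)
  self_cmp <- compare_models(m2, m2)
  expect_equal(self_cmp$delta_aic, 0)
  expect_equal(self_cmp$lrt, 0)
  # nested: distance model vs intercept-only
  m0 <- fit_rejection_glm(d2[, "outcome", drop = FALSE])
  cmp <- compare_models(m0, m2)
  expect_equal(cmp$df, 1)
  expect_equal(cmp$lrt, 2 * (m2$logLik - m0$logLik))
  # a strong true predictor beats intercept-only decisively at n = 500
  exps5 <- generate_experiments(tab, true_coefficients = c(-2, 3),
                                n_experiments = 500, seed = 13,
                                candidates = 1)
  d5 <- build_predictors(make_records(tab, exps5), "distance", std = std)
  big <- fit_rejection_glm(d5)
  null5 <- fit_rejection_glm(d5[, "outcome", drop = FALSE])
  expect_lt(compare_models(big, null5)$delta_aic, -10)
  # non-nested pair refuses the LRT
  m1 <- fit_rejection_glm(build_predictors(rec, "traits",
                                           composites = comps))
  expect_true(is.na(compare_models(m1, m2)$lrt))
})

test_that("hierarchical partitioning splits equal independent effects evenly", {
  set.seed(61)
  n <- 2000
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.8 * x1 + 0.8 * x2))
  pv <- partition_variance(data.frame(outcome = y, x1 = x1, x2 = x2))
  expect_equal(sum(pv), 100, tolerance = 1e-6)
  expect_equal(unname(pv["x1"]), 50, tolerance = 5 / 50)
  one <- partition_variance(data.frame(outcome = y, x1 = x1))
  expect_equal(unname(one), 100)
})

test_that("VIF matches its closed form and the car oracle", {
  set.seed(71)
  n <- 500
  a <- rnorm(n)
  # residualize so the empirical correlation is exactly 0.9
  e <- resid(lm(rnorm(n) ~ a))
  b <- 0.9 * scale(a)[, 1] + sqrt(1 - 0.81) * scale(e)[, 1]
  x <- cbind(a = scale(a)[, 1], b = b)
  expect_equal(cor(x)[1, 2], 0.9, tolerance = 1e-12)
  expect_equal(unname(vif(x)), rep(1 / (1 - 0.81), 2), tolerance = 1e-10)
  expect_equal(unname(vif(x))[1], 5.263, tolerance = 1e-3)
  ortho <- cbind(x = rep(c(1, -1), 4), y = rep(c(1, 1, -1, -1), 2),
                 z = c(rep(1, 4), rep(-1, 4)))
  expect_equal(unname(vif(ortho)), rep(1, 3), tolerance = 1e-10)
  set.seed(3)
  rand <- matrix(rnorm(300), ncol = 3)
  expect_true(all(vif(rand) >= 1))
  # cross-check against the standard regression-model implementation
  colnames(rand) <- c("p", "q", "r")
  df <- as.data.frame(rand)
  df$y <- rnorm(100)
  expect_equal(unname(vif(rand)),
               unname(car::vif(lm(y ~ p + q + r, data = df))),
               tolerance = 1e-8)
  dup <- cbind(u = a, v = a)
  expect_true(all(is.infinite(suppressWarnings(vif(dup)))))
})

test_that("refits on permuted outcomes centre the adjusted R2 near zero", {
  tab <- small_population(seed = 15)
  exps <- generate_experiments(tab, n_experiments = 150, seed = 16)
  rec <- make_records(tab, exps)
  std <- fit_distance_standardization(tab)
  d2 <- build_predictors(rec, "distance", std = std)
  set.seed(17)
  r2s <- vapply(1:30, function(i) {
    perm <- d2
    perm$outcome <- sample(perm$outcome)
    fit_rejection_glm(perm)$mcfadden_r2
  }, numeric(1))
  expect_lt(abs(mean(r2s)), 0.05)
})
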