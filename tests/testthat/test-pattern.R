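test_that("adaptive threshold finds nothing on a constant egg and recovers a disc", {
  img <- generate_egg_image(egg_image_spec(n_spots = 0, seed = 1))
  expect_equal(sum(adaptive_threshold(img, offset = 0.01)), 0)
  # one disc 0.4 darker than ground, offset 0.1: recovered area within 15%
  ctr <- cbind(nrow(img$pixels) / 2, ncol(img$pixels) / 2)
  r_px <- 0.8 * img$scale
  disc <- paint_discs(img, ctr, r_px, darkness = 0.4)
  pat <- adaptive_threshold(disc, window_mm = 3, offset = 0.1)
  expect_equal(sum(pat), pi * r_px^2, tolerance = 0.15)
  # window larger than the egg errors
  expect_error(adaptive_threshold(img, window_mm = 50), "larger than the egg")
})

test_that("pattern metrics ignore everything outside the mask", {
  sp <- egg_image_spec(n_spots = 15, seed = 4)
  img <- generate_egg_image(sp)
  garbage <- img$pixels
  set.seed(1)
  garbage[!img$mask] <- runif(sum(!img$mask))
  img2 <- egg_image(garbage, img$mask, img$scale, img$blunt_pole)
  expect_equal(adaptive_threshold(img, offset = 0.1),
               adaptive_threshold(img2, offset = 0.1))
  g1 <- granularity(img); g2 <- granularity(img2)
  expect_equal(g1$spectrum$energy, g2$spectrum$energy)
  expect_equal(detect_features(img)$n_features,
               detect_features(img2)$n_features)
})

test_that("dispersion indexes blunt-pole concentration", {
  img <- generate_egg_image(egg_image_spec(n_spots = 0, seed = 1))
  # immaculate: proportion 0, dispersion missing
  pd0 <- proportion_and_dispersion(adaptive_threshold(img), img)
  expect_equal(pd0$prop_pattern, 0)
  expect_true(is.na(pd0$dispersion))
  # all pattern in the blunt (equal-area) third -> dispersion = 3
  cols <- col(img$mask)[img$mask]
  q2 <- quantile(cols, 2 / 3, type = 1, names = FALSE)
  pat <- img$mask & col(img$mask) > q2
  pd3 <- proportion_and_dispersion(pat, img)
  # arithmetic oracle: coverage_third / overall = mask area / blunt area,
  # which is 3 exactly for equal-area thirds (up to pixel discreteness)
  expect_equal(pd3$dispersion, sum(img$mask) / sum(pat), tolerance = 1e-12)
  expect_equal(pd3$dispersion, 3, tolerance = 0.05 / 3)
  # uniformly random 20% coverage -> dispersion ~ 1
  set.seed(7)
  rand <- img$mask & matrix(runif(length(img$mask)) < 0.2, nrow(img$mask))
  pdu <- proportion_and_dispersion(rand, img)
  expect_equal(pdu$dispersion, 1, tolerance = 0.1)
})

test_that("granularity peaks in the band containing a grating's period", {
  mask <- eggsig:::ellipse_mask(266, 380)
  m <- matrix(0.5, 266, 380)
  grat <- 0.5 + 0.2 * sin(2 * pi * col(m) / 8)
  grat[!mask] <- NA
  img <- egg_image(grat, mask, scale = 19)
  g <- granularity(img)
  peak_px <- g$peak_size_mm * img$scale
  expect_true(peak_px / sqrt(2) < 8 && 8 <= peak_px * sqrt(2))
  # constant image: all energies zero
  flat <- generate_egg_image(egg_image_spec(n_spots = 0, seed = 1))
  expect_equal(granularity(flat)$total_energy, 0, tolerance = 1e-20)
  # doubling contrast quadruples every band energy
  grat2 <- 0.5 + 0.4 * sin(2 * pi * col(m) / 8)
  grat2[!mask] <- NA
  g2 <- granularity(egg_image(grat2, mask, scale = 19))
  expect_equal(g2$spectrum$energy, 4 * g$spectrum$energy, tolerance = 1e-8)
  expect_error(granularity(img, n_bands = 1), "2 bands")
})

test_that("feature detection counts and sizes known discs", {
  blank <- generate_egg_image(egg_image_spec(n_spots = 0, seed = 1))
  f0 <- detect_features(blank)
  expect_equal(f0$n_features, 0)
  expect_true(is.na(f0$mean_feature_size_mm2))
  sp <- egg_image_spec(n_spots = 20, spot_radius_mean = 0.5,
                       spot_radius_sd = 0, overlap = FALSE, seed = 2)
  img <- generate_egg_image(sp)
  ft <- detect_features(img)
  expect_lte(abs(ft$n_features - 20), 2)
  expect_equal(ft$mean_feature_size_mm2, pi * 0.25, tolerance = 0.3)
  expect_identical(detect_features(img), detect_features(img))
})

test_that("measured traits respond monotonically to generating parameters", {
  mean_over_seeds <- function(field, ...) {
    mean(vapply(1:3, function(s) {
      img <- generate_egg_image(egg_image_spec(..., seed = s))
      pd <- proportion_and_dispersion(adaptive_threshold(img, offset = 0.1),
                                      img)
      if (field == "n_features") detect_features(img)$n_features else
        pd[[field]]
    }, numeric(1)))
  }
  expect_lt(mean_over_seeds("prop_pattern", n_spots = 10),
            mean_over_seeds("prop_pattern", n_spots = 40))
  expect_lt(mean_over_seeds("dispersion", n_spots = 40, pole_bias = 0),
            mean_over_seeds("dispersion", n_spots = 40, pole_bias = 1))
  expect_lt(mean_over_seeds("n_features", n_spots = 8, overlap = FALSE),
            mean_over_seeds("n_features", n_spots = 24, overlap = FALSE))
})

test_that("composite PCs carry the documented sign and centering", {
  set.seed(3)
  n <- 60
  tab <- data.frame(prop_pattern = runif(n, 0, 0.5))
  tab$dispersion <- 1 + rnorm(n, 0, 0.3)           # ~ uncorrelated pair
  tab$contrast <- exp(rnorm(n))
  tab$contrast_var <- tab$contrast * exp(rnorm(n, 0, 0.1))  # correlated pair
  fit <- fit_composites(tab)
  # 2x2 correlation-matrix PCA: PC1 loadings are 1/sqrt(2) in magnitude
  expect_equal(unname(abs(fit$coverage$loadings)), rep(1 / sqrt(2), 2),
               tolerance = 1e-10)
  expect_gt(fit$coverage$loadings["prop_pattern"], 0)
  expect_gt(fit$energy$loadings["contrast"], 0)
  scored <- score_composites(fit, tab)
  expect_equal(mean(scored$pattern_coverage), 0, tolerance = 1e-10)
  expect_equal(mean(scored$pc_energy), 0, tolerance = 1e-10)
  # perfectly correlated pair explains all variance
  tab2 <- tab
  tab2$contrast_var <- 2 * tab2$contrast
  expect_equal(fit_composites(tab2)$energy$var_explained, 1)
  # degenerate input errors
  tab3 <- tab
  tab3$prop_pattern <- 0.2
  expect_error(fit_composites(tab3), "zero variance")
  expect_error(fit_composites(tab[1:2, ]), "at least 3")
})

test_that("pattern distance is the z-scored Euclidean metric", {
  std <- raw_std()
  a <- egg_traits()
  expect_equal(pattern_distance(a, a, std), 0)
  b <- a; b$prop_pattern <- a$prop_pattern + 1
  expect_equal(pattern_distance(a, b, std), 1)
  # hand-computed example: z differences (0.3, -0.4, 1.2, 0, 0.5)
  d <- egg_traits(prop = a$prop_pattern + 0.3, disp = a$dispersion - 0.4,
                  total = a$total_energy + 1.2, sde = a$sd_energy,
                  nf = a$n_features + 0.5)
  expect_equal(pattern_distance(a, d, std),
               sqrt(0.09 + 0.16 + 1.44 + 0 + 0.25), tolerance = 1e-12)
  expect_equal(pattern_distance(a, d, std), 1.393, tolerance = 1e-3)
  # symmetry and triangle inequality on random triples
  set.seed(9)
  for (i in 1:20) {
    x <- egg_traits(runif(1), runif(1, 0.5, 2), runif(1, 0, 3),
                    runif(1, 0, 2), rpois(1, 20))
    y <- egg_traits(runif(1), runif(1, 0.5, 2), runif(1, 0, 3),
                    runif(1, 0, 2), rpois(1, 20))
    z <- egg_traits(runif(1), runif(1, 0.5, 2), runif(1, 0, 3),
                    runif(1, 0, 2), rpois(1, 20))
    expect_equal(pattern_distance(x, y, std), pattern_distance(y, x, std))
    expect_lte(pattern_distance(x, z, std),
               pattern_distance(x, y, std) + pattern_distance(y, z, std) + 1e-12)
  }
})

test_that("immaculate eggs join the 5-D space with uniform dispersion", {
  tab <- small_population(seed = 4)
  expect_true(any(is.na(tab$dispersion)))
  std <- fit_distance_standardization(tab)
  imm <- tab[is.na(tab$dispersion), ][1, ]
  pat <- tab[!is.na(tab$dispersion), ][1, ]
  d <- pattern_distance(imm, pat, std)
  expect_true(is.finite(d) && d > 0)
  # imputed dispersion = 1: an explicit dispersion of 1 gives the same z row
  imm2 <- imm
  imm2$dispersion <- 1
  expect_equal(pattern_distance(imm2, pat, std), d)
})

test_that("measure_pattern summarizes one egg into the table schema", {
  img <- generate_egg_image(egg_image_spec(n_spots = 18, seed = 5))
  row <- measure_pattern(img)
  expect_true(all(c("prop_pattern", "dispersion", "total_energy",
                    "sd_energy", "contrast", "contrast_var", "n_features",
                    "mean_feature_size_mm2") %in% names(row)))
  expect_gt(row$prop_pattern, 0)
  expect_gt(row$n_features, 0)
})
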