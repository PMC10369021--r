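## Synthetic egg populations with female "signature" structure: every trait
## is generated on a latent Gaussian scale (morph mean + female effect +
## egg effect) and then transformed to its natural domain. Females keep one
## morph and one latent effect for life, so between-female variance is large
## relative to within-clutch variance -- the signature regime in which
## repeatability (ICC) of every trait is high.

MORPHS <- c("immaculate", "speckled", "blotched", "erythristic")

## Latent traits, their transforms to the observed scale, and the observed
## column they feed. mean_feature uses a log scale in mm^2.
LATENT_TRAITS <- c("prop", "disp", "total_energy", "sd_energy", "n_features",
                   "contrast", "contrast_var", "mean_feature",
                   "length_mm", "width_mm")

default_morph_means <- function() {
  m <- rbind(
    immaculate  = c(prop = -7,    disp = 0,    total_energy = log(0.3),
                    sd_energy = log(0.12), n_features = -2,
                    contrast = log(0.1), contrast_var = log(0.05),
                    mean_feature = log(0.1), length_mm = 25.5,
                    width_mm = 18.5),
    speckled    = c(-2.2, log(1.05), log(2),   log(0.7),  log1p(40),
                    log(1),   log(0.5),  log(0.15), 25.5, 18.5),
    blotched    = c(-0.85, log(1.35), log(5),  log(1.8),  log1p(15),
                    log(2.5), log(1.2),  log(1.2),  25.5, 18.5),
    erythristic = c(-2.9, log(1.1),  log(1.5), log(0.5),  log1p(20),
                    log(0.8), log(0.4),  log(0.3),  25.5, 18.5))
  colnames(m) <- LATENT_TRAITS
  m
}

default_colour_params <- function() {
  list(
    immaculate  = list(base = 0.62, slope = 0.05, red_amp = 0.02, uv_amp = 0),
    speckled    = list(base = 0.55, slope = 0.06, red_amp = 0.05, uv_amp = 0),
    blotched    = list(base = 0.50, slope = 0.06, red_amp = 0.06, uv_amp = 0),
    erythristic = list(base = 0.42, slope = 0.04, red_amp = 0.28, uv_amp = 0))
}

#' Configuration of a synthetic host/parasite egg population
#'
#' Defines the study conditions the generator emulates: two species with
#' overlapping polymorphic egg phenotypes (four soft morphs), strong
#' female signatures (between-female latent SD well above within-clutch SD,
#' so trait repeatability exceeds the 0.69 regime reported for real
#' clutches), and a shared morph-level trait structure so that mimicry is
#' near-perfect at the population level.
#'
#' @param n_females_host,n_females_parasite number of females per species.
#'   Defaults (166, 28) mirror the study's sample of patterned host eggs
#'   and independent parasite females.
#' @param eggs_per_female clutch size per female (>= 1).
#' @param morph_weights probabilities of the four morphs (immaculate,
#'   speckled, blotched, erythristic) for the host; must sum to 1.
#' @param morph_weights_parasite morph probabilities for the parasite;
#'   defaults to a distribution with more blotched eggs than the host, the
#'   one population-level asymmetry observed in the field.
#' @param between_female_sd,within_female_sd named per-latent-trait SDs of
#'   the female and egg effects.
#' @param morph_trait_means 4 x k matrix of latent trait means by morph.
#' @param colour_params per-morph ground-colour spectral parameters (see
#'   [generate_spectrum()]).
#' @param uv_shoulder_host additional short-UV reflectance shoulder for host
#'   eggs (the host's spectra sit slightly above the parasite's below
#'   ~315 nm).
#' @param seed integer root seed; the generator is a pure function of the
#'   configuration including this seed.
#' @return object of class `population_config`.
#' @export
population_config <- function(n_females_host = 166,
                              n_females_parasite = 28,
                              eggs_per_female = 3,
                              morph_weights = c(0.25, 0.35, 0.20, 0.20),
                              morph_weights_parasite = c(0.20, 0.30, 0.30, 0.20),
                              between_female_sd = NULL,
                              within_female_sd = NULL,
                              morph_trait_means = default_morph_means(),
                              colour_params = default_colour_params(),
                              uv_shoulder_host = 0.05,
                              seed = 1L) {
  between_default <- c(prop = 1.0, disp = 0.22, total_energy = 0.45,
                       sd_energy = 0.45, n_features = 0.5, contrast = 0.45,
                       contrast_var = 0.45, mean_feature = 0.3,
                       length_mm = 0.9, width_mm = 0.6)
  within_default <- c(prop = 0.30, disp = 0.07, total_energy = 0.14,
                      sd_energy = 0.14, n_features = 0.15, contrast = 0.14,
                      contrast_var = 0.14, mean_feature = 0.1,
                      length_mm = 0.3, width_mm = 0.2)
  between_female_sd <- modify_named(between_default, between_female_sd)
  within_female_sd <- modify_named(within_default, within_female_sd)
  stop_if(abs(sum(morph_weights) - 1) > 1e-9,
          "morph_weights must sum to 1")
  stop_if(abs(sum(morph_weights_parasite) - 1) > 1e-9,
          "morph_weights_parasite must sum to 1")
  stop_if(any(morph_weights < 0) || any(morph_weights_parasite < 0),
          "morph weights must be non-negative")
  stop_if(any(between_female_sd < 0) || any(within_female_sd < 0),
          "trait SDs must be non-negative")
  stop_if(!is_count(eggs_per_female) || eggs_per_female < 1,
          "eggs_per_female must be a count >= 1")
  stop_if(!is_count(n_females_host) || !is_count(n_females_parasite),
          "female counts must be non-negative integers")
  stop_if(!all(dim(morph_trait_means) == c(4, length(LATENT_TRAITS))),
          "morph_trait_means must be 4 x %d", length(LATENT_TRAITS))
  structure(list(
    n_females_host = n_females_host,
    n_females_parasite = n_females_parasite,
    eggs_per_female = eggs_per_female,
    morph_weights = morph_weights,
    morph_weights_parasite = morph_weights_parasite,
    between_female_sd = between_female_sd,
    within_female_sd = within_female_sd,
    morph_trait_means = morph_trait_means,
    colour_params = colour_params,
    uv_shoulder_host = uv_shoulder_host,
    seed = as.integer(seed)
  ), class = "population_config")
}

modify_named <- function(default, override) {
  if (is.null(override)) return(default)
  stop_if(is.null(names(override)) || !all(names(override) %in% names(default)),
          "overrides must be named after latent traits: %s",
          paste(names(default), collapse = ", "))
  default[names(override)] <- override
  default
}

#' Generate a synthetic phenotype table
#'
#' Draws a two-species egg population under the configuration's variance
#' structure. For every female: a morph (categorical draw), then one latent
#' female effect per trait (SD `between_female_sd`); for every egg of that
#' female an independent egg effect (SD `within_female_sd`). Latent values
#' are transformed to the observed scale (proportions through the logistic,
#' positive traits through exp, counts rounded at a floor of zero). Eggs
#' with essentially no maculation (proportion below 0.5%) are recorded as
#' immaculate measurements: proportion 0, dispersion and mean feature size
#' missing, zero features. Ground colour is generated per egg from the
#' morph's spectral parameters and summarized as von-Kries cone catches
#' under D65 through the package's default VS receptor set.
#'
#' RNG stream order (single stream from `config$seed`): morph assignments,
#' female effects, egg effects, colour parameter noise. The generator is
#' deterministic given the configuration.
#'
#' @param config a [population_config()].
#' @param receptors receptor set used to summarize colour; default
#'   [vs_receptor_set()].
#' @return a `data.frame` (phenotype table) with one row per egg; columns
#'   `species`, `female_id`, `clutch_id`, `egg_id`, `morph`, `length_mm`,
#'   `width_mm`, `shape_ratio`, `prop_pattern`, `dispersion`,
#'   `total_energy`, `sd_energy`, `n_features`, `mean_feature_size_mm2`,
#'   `contrast`, `contrast_var`, `catch_uv`, `catch_sw`, `catch_mw`,
#'   `catch_lw`, `catch_dbl`.
#' @export
generate_population <- function(config, receptors = vs_receptor_set()) {
  stopifnot(inherits(config, "population_config"))
  n_h <- config$n_females_host
  n_p <- config$n_females_parasite
  stop_if(n_h + n_p == 0, "cannot generate a population with zero females")
  set.seed(config$seed)
  k <- length(LATENT_TRAITS)
  species <- c(rep("host", n_h), rep("parasite", n_p))
  n_f <- n_h + n_p

  ## stream 1: morphs
  morphs <- character(n_f)
  if (n_h > 0)
    morphs[seq_len(n_h)] <- sample(MORPHS, n_h, TRUE, config$morph_weights)
  if (n_p > 0)
    morphs[n_h + seq_len(n_p)] <-
      sample(MORPHS, n_p, TRUE, config$morph_weights_parasite)

  ## stream 2: female effects (n_f x k)
  fem_eff <- matrix(rnorm(n_f * k, 0, rep(config$between_female_sd,
                                          each = n_f)), n_f, k)
  colnames(fem_eff) <- LATENT_TRAITS

  ## stream 3: egg effects
  epf <- config$eggs_per_female
  n_eggs <- n_f * epf
  egg_eff <- matrix(rnorm(n_eggs * k, 0, rep(config$within_female_sd,
                                             each = n_eggs)), n_eggs, k)
  fem_idx <- rep(seq_len(n_f), each = epf)
  latent <- config$morph_trait_means[morphs[fem_idx], , drop = FALSE] +
    fem_eff[fem_idx, , drop = FALSE] + egg_eff

  ## stream 4: colour noise (per female base shift, per egg jitter)
  base_fem <- rnorm(n_f, 0, 0.04)
  red_fem <- rnorm(n_f, 0, 0.03)
  base_egg <- rnorm(n_eggs, 0, 0.01)

  prop <- plogis(latent[, "prop"])
  nfeat <- round(pmax(expm1(latent[, "n_features"]), 0))
  immac <- prop < 0.005 | nfeat == 0
  prop[immac] <- 0
  nfeat[immac] <- 0L
  disp <- exp(latent[, "disp"])
  disp[immac] <- NA_real_
  mfs <- exp(latent[, "mean_feature"])
  mfs[immac] <- NA_real_

  tab <- data.frame(
    species = species[fem_idx],
    female_id = sprintf("%s_F%03d", species[fem_idx], fem_idx),
    clutch_id = sprintf("%s_C%03d", species[fem_idx], fem_idx),
    egg_id = sprintf("%s_F%03d_E%d", species[fem_idx], fem_idx,
                     rep(seq_len(epf), n_f)),
    morph = morphs[fem_idx],
    length_mm = latent[, "length_mm"],
    width_mm = latent[, "width_mm"],
    prop_pattern = prop,
    dispersion = disp,
    total_energy = exp(latent[, "total_energy"]),
    sd_energy = exp(latent[, "sd_energy"]),
    n_features = as.integer(nfeat),
    mean_feature_size_mm2 = mfs,
    contrast = exp(latent[, "contrast"]),
    contrast_var = exp(latent[, "contrast_var"]),
    stringsAsFactors = FALSE)
  tab$shape_ratio <- tab$width_mm / tab$length_mm

  ## colour: one spectrum per egg -> von Kries cone catches, vectorized as
  ## one matrix product of the spectra against the integration weights
  wl <- receptors$wavelengths
  irr <- d65(wl)$irradiance
  cp <- config$colour_params
  base <- pmax(vapply(morphs, function(m) cp[[m]]$base, 1)[fem_idx] +
                 base_fem[fem_idx] + base_egg, 0.05)
  slope <- vapply(morphs, function(m) cp[[m]]$slope, 1)[fem_idx]
  red <- pmax(vapply(morphs, function(m) cp[[m]]$red_amp, 1)[fem_idx] +
                red_fem[fem_idx], 0)
  uv <- vapply(morphs, function(m) cp[[m]]$uv_amp, 1)[fem_idx] +
    ifelse(species[fem_idx] == "host", config$uv_shoulder_host, 0)
  spectra <- outer(base, rep(1, length(wl))) +
    outer(slope, (wl - 500) / 200) +
    outer(red, plogis((wl - 590) / 20)) +
    outer(uv, exp(-((wl - 308) / 10)^2))
  stop_if(any(spectra < 0) || any(spectra > 1),
          "colour parameters produce reflectance outside [0, 1]")
  ## trapezoid weights on the common grid
  tw <- c(diff(wl) / 2, 0) + c(0, diff(wl) / 2)
  w_int <- receptors$sensitivities * irr * tw          # grid x channels
  raw <- spectra %*% w_int                             # eggs x channels
  white <- colSums(w_int)
  catches <- sweep(raw, 2, white, "/")
  colnames(catches) <- c("catch_uv", "catch_sw", "catch_mw", "catch_lw",
                         "catch_dbl")
  cbind(tab, as.data.frame(catches))
}

#' Generate a smooth ground-colour reflectance spectrum
#'
#' Parametric eggshell ground colour: a baseline plus gentle linear slope,
#' a long-wavelength logistic shoulder (elevated in erythristic, i.e.
#' reddish-brown, morphs) and an optional Gaussian UV shoulder near 308 nm.
#'
#' @param params list with `base`, `slope`, `red_amp`, `uv_amp` (missing
#'   entries default to 0; `base` to 0.5).
#' @param wavelengths nm grid, default 300-700 at 1 nm.
#' @return a [reflectance_spectrum()].
#' @export
#' @examples
#' s <- generate_spectrum(list(base = 0.5))
#' range(s$reflectance)  # constant 0.5
generate_spectrum <- function(params, wavelengths = 300:700) {
  base <- params$base %||% 0.5
  slope <- params$slope %||% 0
  red <- params$red_amp %||% 0
  uv <- params$uv_amp %||% 0
  wl <- wavelengths
  r <- base + slope * (wl - 500) / 200 + red * plogis((wl - 590) / 20) +
    uv * exp(-((wl - 308) / 10)^2)
  stop_if(any(r < 0), "parameters produce negative reflectance (min %.3f)",
          min(r))
  stop_if(any(r > 1), "parameters produce reflectance > 1 (max %.3f)", max(r))
  reflectance_spectrum(wl, r)
}
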