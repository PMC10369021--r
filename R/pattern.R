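## Eggshell pattern quantification from masked grayscale images: mask-aware
## adaptive thresholding, pole-dispersion, FFT band-pass granularity, and
## the population-level composite metrics and multidimensional pattern
## distance built on the measured traits.

## The five traits defining multidimensional pattern space: measures that
## are reliable for both immaculate and patterned eggs (mean feature size is
## excluded because it is erroneous for immaculate eggs).
DISTANCE_TRAITS <- c("prop_pattern", "dispersion", "total_energy",
                     "sd_energy", "n_features")

## 2-D moving-window sum via integral images; window = (2r+1) square.
box_sum <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 1, nc + 1)
  p[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))  # 2-D integral image
  lo_r <- pmax(seq_len(nr) - r - 1, 0) + 1
  hi_r <- pmin(seq_len(nr) + r, nr) + 1
  lo_c <- pmax(seq_len(nc) - r - 1, 0) + 1
  hi_c <- pmin(seq_len(nc) + r, nc) + 1
  p[hi_r, hi_c] - p[lo_r, hi_c] - p[hi_r, lo_c] + p[lo_r, lo_c]
}

#' Adaptive threshold of an egg image
#'
#' Classifies pixels as "pattern" when they are darker than the local
#' mask-aware mean by more than `offset`: pattern only ever means dark
#' markings on a paler ground. The local mean at each pixel is computed
#' over a square window of `window_mm`, counting only in-mask pixels, so
#' values outside the egg never influence the classification.
#'
#' @param img an [egg_image()].
#' @param window_mm side of the local averaging window, in mm (default 3).
#' @param offset how far (in brightness units) below the local mean a pixel
#'   must be to count as pattern.
#' @return logical matrix: `TRUE` for pattern pixels (always `FALSE`
#'   outside the egg mask).
#' @export
adaptive_threshold <- function(img, window_mm = 3, offset = 0.05) {
  stopifnot(inherits(img, "egg_image"))
  w_px <- max(round(window_mm * img$scale), 3)
  r <- max(floor(w_px / 2), 1)
  bb <- which(img$mask, arr.ind = TRUE)
  extent <- max(diff(range(bb[, 1])), diff(range(bb[, 2]))) + 1
  stop_if(w_px > extent, "window (%d px) larger than the egg extent (%d px)",
          w_px, extent)
  pix0 <- img$pixels
  pix0[!img$mask | is.na(pix0)] <- 0
  m01 <- matrix(as.numeric(img$mask), nrow(pix0))
  local_mean <- box_sum(pix0, r) / pmax(box_sum(m01, r), 1)
  pat <- img$mask & (img$pixels < local_mean - offset)
  pat[is.na(pat)] <- FALSE
  pat
}

#' Proportion of pattern and pole dispersion
#'
#' `prop_pattern` is the fraction of in-mask pixels classified as pattern.
#' `dispersion` indexes concentration of markings at the blunt pole: the
#' egg is split into three equal-area bands along the major axis (terciles
#' of the in-mask column distribution) and dispersion is pattern coverage
#' in the blunt-pole band divided by overall coverage. 1 means uniform
#' placement; 3 means all markings sit in the blunt third. Missing (`NA`)
#' for immaculate eggs (no pattern pixels).
#'
#' @param pattern_mask logical matrix from [adaptive_threshold()].
#' @param img the corresponding [egg_image()].
#' @return named list with `prop_pattern` and `dispersion`.
#' @export
proportion_and_dispersion <- function(pattern_mask, img) {
  stopifnot(inherits(img, "egg_image"))
  mask <- img$mask
  stop_if(sum(mask) == 0, "empty egg mask")
  prop <- sum(pattern_mask & mask) / sum(mask)
  if (prop == 0) return(list(prop_pattern = 0, dispersion = NA_real_))
  cols <- col(mask)[mask]
  qs <- quantile(cols, c(1 / 3, 2 / 3), type = 1, names = FALSE)
  blunt <- if (img$blunt_pole == "right") col(mask) > qs[2] else
    col(mask) < qs[1]
  cov_blunt <- sum(pattern_mask & mask & blunt) / sum(mask & blunt)
  list(prop_pattern = prop, dispersion = cov_blunt / prop)
}

## FFT band-pass filter: keep spatial wavelengths (px) in (lo, hi].
fft_bandpass <- function(fmat, lo, hi) {
  nr <- nrow(fmat); nc <- ncol(fmat)
  fy <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1) / nr
  fx <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1) / nc
  fr <- sqrt(outer(fy^2, fx^2, "+"))
  keep <- fr > 1 / hi & fr <= 1 / lo
  Re(stats::fft(fmat * keep, inverse = TRUE)) / (nr * nc)
}

#' Granularity spectrum of an egg image
#'
#' Band-pass decomposition of the egg into octave-spaced marking-size
#' scales. The image is filled with its in-mask mean outside the mask,
#' Fourier-filtered into bands whose spatial wavelengths straddle each
#' nominal size (geometric octave band: wavelengths within a factor
#' `sqrt(ratio)` of the size), and the energy of each band is the variance
#' of the filtered pixels inside the mask.
#'
#' @param img an [egg_image()].
#' @param n_bands number of bands (>= 2); default 7.
#' @param min_size_mm,max_size_mm smallest and largest nominal marking size
#'   (mm). Defaults 0.25 and 16 give the classic 7 octave bands at
#'   19 px/mm.
#' @return object of class `granularity_spectrum`: data frame of
#'   `size_mm`/`energy` plus summary fields `total_energy` (sum of band
#'   energies), `sd_energy` (SD across bands), `contrast` (maximum band
#'   energy), `contrast_var` (SD of the band-summed image inside the mask)
#'   and `peak_size_mm`.
#' @export
granularity <- function(img, n_bands = 7, min_size_mm = 0.25,
                        max_size_mm = 16) {
  stopifnot(inherits(img, "egg_image"))
  stop_if(n_bands < 2, "granularity needs at least 2 bands")
  stop_if(min_size_mm <= 0 || max_size_mm <= min_size_mm,
          "need 0 < min_size_mm < max_size_mm")
  sizes_mm <- exp(seq(log(min_size_mm), log(max_size_mm),
                      length.out = n_bands))
  ratio <- sizes_mm[2] / sizes_mm[1]
  sizes_px <- sizes_mm * img$scale
  fill <- mean(img$pixels[img$mask])
  f <- img$pixels
  f[!img$mask | is.na(f)] <- fill
  fmat <- stats::fft(f)
  bands <- lapply(sizes_px, function(s)
    fft_bandpass(fmat, s / sqrt(ratio), s * sqrt(ratio)))
  energies <- vapply(bands, function(b) var(b[img$mask]), numeric(1))
  summed <- Reduce(`+`, bands)
  structure(list(
    spectrum = data.frame(size_mm = sizes_mm, energy = energies),
    total_energy = sum(energies),
    sd_energy = sd(energies),
    contrast = max(energies),
    contrast_var = sd(summed[img$mask]),
    peak_size_mm = sizes_mm[which.max(energies)]
  ), class = "granularity_spectrum")
}

#' @export
print.granularity_spectrum <- function(x, ...) {
  cat("<granularity_spectrum>\n")
  print(x$spectrum, row.names = FALSE)
  cat(sprintf("total %.4g  sd %.4g  contrast %.4g (at %.3g mm)  contrast_var %.4g\n",
              x$total_energy, x$sd_energy, x$contrast, x$peak_size_mm,
              x$contrast_var))
  invisible(x)
}

#' Measure all pattern traits of one egg image
#'
#' Convenience wrapper running [adaptive_threshold()],
#' [proportion_and_dispersion()], [granularity()] and [detect_features()]
#' with shared defaults, returning one row of the phenotype-table pattern
#' schema.
#'
#' @param img an [egg_image()].
#' @param window_mm,offset adaptive threshold parameters.
#' @param ... passed to [detect_features()].
#' @return one-row `data.frame` with the pattern trait columns.
#' @export
measure_pattern <- function(img, window_mm = 3, offset = 0.05, ...) {
  pat <- adaptive_threshold(img, window_mm, offset)
  pd <- proportion_and_dispersion(pat, img)
  gr <- granularity(img)
  ft <- detect_features(img, ...)
  data.frame(prop_pattern = pd$prop_pattern, dispersion = pd$dispersion,
             total_energy = gr$total_energy, sd_energy = gr$sd_energy,
             contrast = gr$contrast, contrast_var = gr$contrast_var,
             n_features = ft$n_features,
             mean_feature_size_mm2 = ft$mean_feature_size_mm2)
}

#' Fit the population-level composite pattern metrics
#'
#' Two correlation-matrix principal component analyses over the table:
#' `pattern_coverage` is PC1 of (proportion pattern, dispersion) --- how
#' much of the egg is covered and how those markings are distributed ---
#' and `pc_energy` is PC1 of (pattern contrast, contrast variability).
#' Missing dispersion (immaculate eggs) is imputed as 1 (uniform) before
#' fitting. Signs are fixed so pattern_coverage rises with proportion
#' pattern and pc_energy with contrast; standardization statistics are
#' retained for out-of-sample scoring.
#'
#' @param table phenotype table with columns `prop_pattern`, `dispersion`,
#'   `contrast`, `contrast_var`.
#' @return object of class `composite_fit` with elements `coverage` and
#'   `energy` (each: `center`, `scale`, `loadings`, `var_explained`).
#' @export
fit_composites <- function(table) {
  stop_if(nrow(table) < 3, "need at least 3 eggs to fit composites")
  tab <- impute_immaculate(table)
  fit_pair <- function(x, positive_on) {
    stop_if(any(apply(x, 2, sd) == 0), "zero variance in composite input %s",
            paste(colnames(x)[apply(x, 2, sd) == 0], collapse = ", "))
    pc <- prcomp(x, center = TRUE, scale. = TRUE)
    load <- pc$rotation[, 1]
    if (load[positive_on] < 0) load <- -load
    list(center = pc$center, scale = pc$scale, loadings = load,
         var_explained = pc$sdev[1]^2 / sum(pc$sdev^2))
  }
  structure(list(
    coverage = fit_pair(as.matrix(tab[, c("prop_pattern", "dispersion")]),
                        "prop_pattern"),
    energy = fit_pair(as.matrix(tab[, c("contrast", "contrast_var")]),
                      "contrast")
  ), class = "composite_fit")
}

#' Score composite metrics for a table
#' @param fit a `composite_fit`.
#' @param table phenotype table (any population).
#' @return `table` with columns `pattern_coverage` and `pc_energy` added.
#' @export
score_composites <- function(fit, table) {
  stopifnot(inherits(fit, "composite_fit"))
  tab <- impute_immaculate(table)
  score1 <- function(p, x)
    drop(scale(x, p$center, p$scale) %*% p$loadings)
  table$pattern_coverage <-
    score1(fit$coverage, as.matrix(tab[, c("prop_pattern", "dispersion")]))
  table$pc_energy <-
    score1(fit$energy, as.matrix(tab[, c("contrast", "contrast_var")]))
  table
}

## Immaculate eggs carry prop_pattern 0 and missing dispersion / feature
## size; the 5-D space keeps them by treating their placement as uniform.
impute_immaculate <- function(table) {
  if ("dispersion" %in% names(table))
    table$dispersion[is.na(table$dispersion)] <- 1
  table
}

#' Fit the standardization for multidimensional pattern distance
#'
#' Records per-trait means and SDs of the five distance traits over a
#' reference population (by default the pooled host + parasite table of
#' the analysis at hand), after imputing dispersion = 1 for immaculate
#' eggs. With `mode = "raw"` the standardization is the identity (unit
#' scale), i.e. distances are taken in raw trait units.
#'
#' @param table phenotype table containing the five distance traits.
#' @param mode `"z"` (pooled z-scoring, default) or `"raw"`.
#' @return object of class `distance_standardization`.
#' @export
fit_distance_standardization <- function(table, mode = c("z", "raw")) {
  mode <- match.arg(mode)
  tab <- impute_immaculate(table)
  miss <- setdiff(DISTANCE_TRAITS, names(tab))
  stop_if(length(miss) > 0, "table lacks distance traits: %s",
          paste(miss, collapse = ", "))
  x <- as.matrix(tab[, DISTANCE_TRAITS])
  stop_if(any(!is.finite(x)), "non-finite trait values after imputation")
  if (mode == "z") {
    center <- colMeans(x)
    scl <- apply(x, 2, sd)
    stop_if(any(scl <= 0), "zero SD in distance trait %s",
            paste(DISTANCE_TRAITS[scl <= 0], collapse = ", "))
  } else {
    center <- setNames(rep(0, ncol(x)), DISTANCE_TRAITS)
    scl <- setNames(rep(1, ncol(x)), DISTANCE_TRAITS)
  }
  structure(list(center = center, scale = scl, mode = mode,
                 n = nrow(x)), class = "distance_standardization")
}

## Extract, impute and standardize the 5 distance traits of rows of a table
## (or of a single named list/vector).
z_traits <- function(x, std) {
  stopifnot(inherits(std, "distance_standardization"))
  if (is.null(dim(x))) x <- as.data.frame(as.list(unlist(x[DISTANCE_TRAITS])))
  x <- impute_immaculate(as.data.frame(x))
  m <- as.matrix(x[, DISTANCE_TRAITS, drop = FALSE])
  sweep(sweep(m, 2, std$center), 2, std$scale, "/")
}

#' Multidimensional pattern distance between two eggs
#'
#' Euclidean distance in the five-dimensional pattern space (proportion
#' pattern, dispersion, total energy, SD energy, number of features),
#' after the standardization in `std`. Immaculate eggs participate with
#' proportion 0 and dispersion imputed as 1.
#'
#' @param a,b named lists, vectors or one-row data frames carrying the five
#'   distance traits.
#' @param std a [fit_distance_standardization()] object.
#' @return non-negative scalar; 0 iff the standardized traits are equal.
#' @export
pattern_distance <- function(a, b, std) {
  za <- z_traits(a, std)
  zb <- z_traits(b, std)
  sqrt(sum((za - zb)^2))
}

## Vectorized distances between paired rows of two tables.
pattern_distance_rows <- function(ta, tb, std) {
  za <- z_traits(ta, std)
  zb <- z_traits(tb, std)
  sqrt(rowSums((za - zb)^2))
}
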