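## Avian colour vision: quantum catches and receptor-noise-limited
## discrimination distances (JNDs).

#' Reflectance spectrum constructor
#'
#' @param wavelengths strictly increasing nm grid (typically 300-700 at 1 nm).
#' @param reflectance reflectance in `[0, 1]`-ish units (must be >= 0), one
#'   value per wavelength.
#' @param id optional egg identifier.
#' @return object of class `reflectance_spectrum`.
#' @export
reflectance_spectrum <- function(wavelengths, reflectance, id = NULL) {
  stop_if(any(diff(wavelengths) <= 0), "wavelength grid must be increasing")
  stop_if(length(reflectance) != length(wavelengths),
          "reflectance and wavelengths differ in length")
  stop_if(any(!is.finite(reflectance)), "reflectance must be finite")
  stop_if(any(reflectance < 0), "reflectance must be non-negative")
  structure(list(wavelengths = wavelengths, reflectance = reflectance,
                 id = id), class = "reflectance_spectrum")
}

#' Predicted cone quantum catches of a reflectance spectrum
#'
#' Integrates reflectance x illuminant x receptor sensitivity over the
#' receptor set's wavelength grid (trapezoid rule; spectrum and illuminant
#' are linearly interpolated onto that grid). With `normalize = TRUE` the
#' catches are von-Kries normalized: each channel is divided by the catch of
#' a perfect white (unit reflectance) under the same illuminant, so an ideal
#' white yields catch 1 in every channel.
#'
#' @param spectrum a [reflectance_spectrum()].
#' @param receptors a [receptor_set()].
#' @param illum an [illuminant()]; default [d65()].
#' @param normalize apply von Kries normalization (default `TRUE`).
#' @return object of class `cone_catches`: named list of single-cone catches
#'   plus `dbl`, the luminance (double cone) catch.
#' @export
#' @examples
#' r <- vs_receptor_set()
#' s <- reflectance_spectrum(300:700, rep(0.5, 401))
#' cone_catch(s, r)
cone_catch <- function(spectrum, receptors, illum = d65(), normalize = TRUE) {
  stopifnot(inherits(spectrum, "reflectance_spectrum"),
            inherits(receptors, "receptor_set"),
            inherits(illum, "illuminant"))
  wl <- receptors$wavelengths
  refl <- interp_to_grid(spectrum$wavelengths, spectrum$reflectance, wl)
  irr <- interp_to_grid(illum$wavelengths, illum$irradiance, wl)
  sens <- receptors$sensitivities
  raw <- apply(sens, 2, function(sn) trapz(wl, refl * irr * sn))
  if (normalize) {
    white <- apply(sens, 2, function(sn) trapz(wl, irr * sn))
    stop_if(any(white <= 0), "illuminant gives zero white catch")
    raw <- raw / white
  }
  k <- length(raw)
  structure(c(as.list(raw[-k]), list(dbl = unname(raw[k]))),
            names = c(colnames(sens)[-k], "dbl"),
            class = "cone_catches")
}

#' @export
print.cone_catches <- function(x, ...) {
  v <- unlist(x)
  cat("<cone_catches>", paste(sprintf("%s=%.4g", names(v), v),
                              collapse = "  "), "\n")
  invisible(x)
}

single_catches <- function(x) {
  v <- unlist(x)
  v[setdiff(names(v), "dbl")]
}

receptor_noise <- function(receptors) {
  d <- receptors$relative_densities
  receptors$weber_fraction * sqrt(max(d) / d)
}

#' Chromatic contrast in just-noticeable differences
#'
#' Receptor-noise-limited colour distance between two stimuli for the
#' single-cone channels of `receptors`. Signals are log quantum-catch
#' ratios, `df_i = ln(a_i / b_i)`; channel noise is
#' `e_i = w * sqrt(d_max / d_i)` with `w` the Weber fraction of the most
#' abundant cone. Supports di-, tri- and tetrachromatic receptor sets.
#' A value below 1 JND means the two colours are predicted to be
#' indiscriminable to the modelled viewer.
#'
#' @param a,b `cone_catches` of the two stimuli (strictly positive).
#' @param receptors the [receptor_set()] supplying the noise model.
#' @return non-negative scalar distance in JND units; symmetric in `a`, `b`
#'   and invariant to a common intensity scaling of both stimuli.
#' @export
chromatic_jnd <- function(a, b, receptors) {
  qa <- single_catches(a); qb <- single_catches(b)
  stop_if(length(qa) != length(qb), "catch vectors differ in length")
  stop_if(any(qa <= 0) || any(qb <= 0),
          "zero or negative cone catch: log signal undefined")
  e <- receptor_noise(receptors)
  stop_if(length(e) != length(qa),
          "receptor set has %d single cones but catches have %d",
          length(e), length(qa))
  df <- log(qa / qb)
  n <- length(df)
  if (n == 2) {
    return(unname(abs(df[1] - df[2]) / sqrt(sum(e^2))))
  }
  if (n == 3) {
    num <- e[1]^2 * (df[3] - df[2])^2 + e[2]^2 * (df[3] - df[1])^2 +
      e[3]^2 * (df[2] - df[1])^2
    den <- (e[1] * e[2])^2 + (e[1] * e[3])^2 + (e[2] * e[3])^2
    return(unname(sqrt(num / den)))
  }
  if (n == 4) {
    num <- (e[1] * e[2])^2 * (df[4] - df[3])^2 +
      (e[1] * e[3])^2 * (df[4] - df[2])^2 +
      (e[1] * e[4])^2 * (df[3] - df[2])^2 +
      (e[2] * e[3])^2 * (df[4] - df[1])^2 +
      (e[2] * e[4])^2 * (df[3] - df[1])^2 +
      (e[3] * e[4])^2 * (df[2] - df[1])^2
    den <- (e[1] * e[2] * e[3])^2 + (e[1] * e[2] * e[4])^2 +
      (e[1] * e[3] * e[4])^2 + (e[2] * e[3] * e[4])^2
    return(unname(sqrt(num / den)))
  }
  stop("chromatic_jnd supports 2-4 single cones", call. = FALSE)
}

#' Achromatic (luminance) contrast in JNDs
#'
#' Log-ratio luminance signal through the double cone divided by the
#' achromatic Weber fraction: `|ln(a_dbl / b_dbl)| / w_ach`.
#'
#' @inheritParams chromatic_jnd
#' @return non-negative scalar, symmetric in `a` and `b`.
#' @export
achromatic_jnd <- function(a, b, receptors) {
  stop_if(a$dbl <= 0 || b$dbl <= 0, "zero double-cone catch")
  abs(log(a$dbl / b$dbl)) / receptors$weber_fraction_achromatic
}

## Regular tetrahedron vertices for tetrahedral colour space (uv apex at
## +z); rows in channel order uv, sw, mw, lw.
tcs_vertices <- rbind(
  uv = c(0, 0, 0.75),
  sw = c(-sqrt(6) / 4, -sqrt(2) / 4, -0.25),
  mw = c(sqrt(6) / 4, -sqrt(2) / 4, -0.25),
  lw = c(0, sqrt(2) / 2, -0.25))

#' Tetrahedral colour-space coordinates
#'
#' Maps relative single-cone catches (proportions summing to 1) to Cartesian
#' coordinates of a regular tetrahedron with the UV channel at the apex.
#'
#' @param catches a `cone_catches` object (tetrachromatic).
#' @return numeric xyz coordinates.
#' @export
tcs_coords <- function(catches) {
  q <- single_catches(catches)
  stop_if(length(q) != 4, "tetrahedral coordinates need 4 single cones")
  stop_if(sum(q) <= 0, "all-zero catches")
  rel <- q / sum(q)
  drop(rel %*% tcs_vertices)
}

#' Population centroid in tetrahedral colour space
#'
#' Averages the tetrahedral chromaticity coordinates of a set of stimuli and
#' maps the mean point back to relative cone catches (the barycentric
#' coordinates of the mean). The luminance channel is averaged
#' arithmetically. With a single stimulus the centroid is that stimulus's
#' relative form.
#'
#' @param catch_list non-empty list of `cone_catches`.
#' @return a `cone_catches` object holding relative single-cone catches
#'   (summing to 1) and the mean double-cone catch.
#' @export
colour_centroid <- function(catch_list) {
  stop_if(length(catch_list) == 0, "empty list of cone catches")
  xyz <- t(vapply(catch_list, tcs_coords, numeric(3)))
  centre <- colMeans(xyz)
  ## invert the barycentric map: rel %*% vertices = centre, sum(rel) = 1
  a <- rbind(t(tcs_vertices), rep(1, 4))
  rel <- drop(solve(a, c(centre, 1)))
  names(rel) <- rownames(tcs_vertices)
  dbl <- mean(vapply(catch_list, function(x) x$dbl, numeric(1)))
  structure(c(as.list(rel), list(dbl = dbl)), class = "cone_catches")
}
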