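## Built-in visual-system data: a violet-sensitive (VS) tetrachromat receptor
## set built from the Govardovskii et al. (2000) A1 visual-pigment template,
## and the CIE standard daylight illuminant D65.

#' Visual pigment absorbance template (A1 chromophore)
#'
#' Govardovskii et al. (2000) rhodopsin template: an alpha band expressed in
#' normalized wavenumber plus a Gaussian beta band. Widely used to construct
#' cone spectral sensitivities when only the pigment's wavelength of maximum
#' absorbance is known.
#'
#' @param wl wavelengths (nm) at which to evaluate the template.
#' @param lambda_max wavelength of maximum absorbance (nm).
#' @return absorbance values in `[0, 1]` at `wl` (peak normalized to 1).
#' @export
#' @examples
#' s <- pigment_template(300:700, 537)
#' 300:700[which.max(s)]  # close to 537
pigment_template <- function(wl, lambda_max) {
  stop_if(!is.numeric(lambda_max) || lambda_max <= 0, "lambda_max must be > 0")
  x <- lambda_max / wl
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lambda_max
  b <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((wl - lmb) / b)^2)
  pmax(alpha + beta, 0)
}

#' Construct a receptor set for the receptor-noise-limited model
#'
#' Bundles cone spectral sensitivities with the relative cone densities and
#' Weber fractions that parameterize receptor noise. Each sensitivity curve
#' is normalized to unit area (trapezoid rule) so cone catches are on a
#' comparable scale across channels.
#'
#' @param wavelengths wavelength grid in nm (strictly increasing).
#' @param sensitivities matrix or data frame with one column per receptor
#'   channel; single cones first, the double (luminance) cone last. Column
#'   names are kept as channel labels.
#' @param relative_densities relative abundances of the single cones, in the
#'   column order of `sensitivities` (excluding the double cone).
#' @param weber_fraction Weber fraction of the most abundant single cone.
#' @param weber_fraction_achromatic Weber fraction of the luminance channel.
#' @param label free-text label for reports.
#' @return an object of class `receptor_set`.
#' @export
receptor_set <- function(wavelengths, sensitivities, relative_densities,
                         weber_fraction = 0.1,
                         weber_fraction_achromatic = 0.34,
                         label = "custom") {
  sensitivities <- as.matrix(sensitivities)
  stop_if(any(diff(wavelengths) <= 0), "wavelength grid must be increasing")
  stop_if(nrow(sensitivities) != length(wavelengths),
          "sensitivities must have one row per wavelength")
  stop_if(any(sensitivities < 0), "sensitivities must be non-negative")
  areas <- apply(sensitivities, 2, function(y) trapz(wavelengths, y))
  stop_if(any(areas <= 0), "each sensitivity curve must have positive area")
  sensitivities <- sweep(sensitivities, 2, areas, "/")
  n_single <- ncol(sensitivities) - 1
  stop_if(length(relative_densities) != n_single,
          "need one relative density per single cone (%d)", n_single)
  stop_if(any(relative_densities <= 0), "densities must be positive")
  stop_if(weber_fraction <= 0 || weber_fraction_achromatic <= 0,
          "Weber fractions must be positive")
  structure(list(
    wavelengths = wavelengths,
    sensitivities = sensitivities,
    relative_densities = relative_densities,
    weber_fraction = weber_fraction,
    weber_fraction_achromatic = weber_fraction_achromatic,
    label = label
  ), class = "receptor_set")
}

#' @export
print.receptor_set <- function(x, ...) {
  cat("<receptor_set>", x$label, "\n")
  cat("  channels:", paste(colnames(x$sensitivities), collapse = ", "), "\n")
  cat("  densities:", paste(x$relative_densities, collapse = ":"),
      " weber:", x$weber_fraction,
      " weber (achromatic):", x$weber_fraction_achromatic, "\n")
  invisible(x)
}

#' Default violet-sensitive tetrachromat receptor set
#'
#' A VS-type avian visual system assembled from the A1 pigment template with
#' peak sensitivities 432 (VS/UV channel), 477 (SW), 537 (MW) and 605 nm
#' (LW), plus a 567 nm double cone for the luminance channel. Relative cone
#' densities default to 1:2:2:4 (UV:SW:MW:LW) with a Weber fraction of 0.1
#' on the most abundant cone and 0.34 on the luminance channel. All values
#' are configurable; the object records them for reporting.
#'
#' @param wavelengths wavelength grid, default 300-700 nm at 1 nm.
#' @param lambda_max peak wavelengths of the four single cones and the
#'   double cone, in nm.
#' @param relative_densities,weber_fraction,weber_fraction_achromatic noise
#'   model parameters, see [receptor_set()].
#' @return a `receptor_set`.
#' @export
#' @examples
#' r <- vs_receptor_set()
#' r
vs_receptor_set <- function(wavelengths = 300:700,
                            lambda_max = c(uv = 432, sw = 477, mw = 537,
                                           lw = 605, dbl = 567),
                            relative_densities = c(1, 2, 2, 4),
                            weber_fraction = 0.1,
                            weber_fraction_achromatic = 0.34) {
  sens <- vapply(lambda_max, function(lm) pigment_template(wavelengths, lm),
                 numeric(length(wavelengths)))
  receptor_set(wavelengths, sens, relative_densities,
               weber_fraction, weber_fraction_achromatic,
               label = "VS tetrachromat (A1 template)")
}

## CIE standard illuminant D65, relative spectral power (energy units),
## 300-700 nm at 5 nm steps.
d65_wl_5nm <- seq(300, 700, by = 5)
d65_spd_5nm <- c(
  0.0341, 1.6643, 3.2945, 11.7652, 20.236, 28.6447, 37.0535, 38.5011,
  39.9488, 42.4302, 44.9117, 45.775, 46.6383, 49.3637, 52.0891, 51.0323,
  49.9755, 52.3118, 54.6482, 68.7015, 82.7549, 87.1204, 91.486, 92.4589,
  93.4318, 90.057, 86.6823, 95.7736, 104.865, 110.936, 117.008, 117.41,
  117.812, 116.336, 114.861, 115.392, 115.923, 112.367, 108.811, 109.082,
  109.354, 108.578, 107.802, 106.296, 104.79, 106.239, 107.689, 106.047,
  104.405, 104.225, 104.046, 102.023, 100.0, 98.1671, 96.3342, 96.0611,
  95.788, 92.2368, 88.6856, 89.3459, 90.0062, 89.8026, 89.5991, 88.6489,
  87.6987, 85.4936, 83.2886, 83.4939, 83.6992, 81.863, 80.0268, 80.1207,
  80.2146, 81.2462, 82.2778, 80.281, 78.2842, 74.0027, 69.7213, 70.6652,
  71.6091)

#' Illuminant constructor
#'
#' @param wavelengths nm grid.
#' @param irradiance relative irradiance in quantum units (photons), one
#'   value per wavelength, non-negative.
#' @param label free-text label.
#' @return object of class `illuminant`.
#' @export
illuminant <- function(wavelengths, irradiance, label = "custom") {
  stop_if(any(diff(wavelengths) <= 0), "wavelength grid must be increasing")
  stop_if(length(irradiance) != length(wavelengths),
          "irradiance and wavelengths differ in length")
  stop_if(any(irradiance < 0), "irradiance must be non-negative")
  structure(list(wavelengths = wavelengths, irradiance = irradiance,
                 label = label), class = "illuminant")
}

#' Standard daylight illuminant D65
#'
#' CIE D65 interpolated to the requested grid and converted from energy to
#' relative quantum units (multiplied by wavelength, then rescaled to peak 1),
#' as appropriate for quantum-catch calculations.
#'
#' @param wavelengths target grid (nm), within 300-700.
#' @return an `illuminant`.
#' @export
d65 <- function(wavelengths = 300:700) {
  spd <- interp_to_grid(d65_wl_5nm, d65_spd_5nm, wavelengths)
  q <- spd * wavelengths
  illuminant(wavelengths, q / max(q), label = "D65 (quantum units)")
}

#' Ideal flat illuminant
#' @param wavelengths target grid (nm).
#' @return an `illuminant` with unit irradiance everywhere.
#' @export
flat_illuminant <- function(wavelengths = 300:700) {
  illuminant(wavelengths, rep(1, length(wavelengths)), label = "flat")
}
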