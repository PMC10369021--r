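## Synthetic egg photographs: a grayscale egg (ellipse mask inscribed in
## the frame) with dark circular maculation, used as ground-truth fixtures
## for the pattern operators. Coordinate convention (used package-wide):
## images are matrices indexed [row, column], origin top-left; the egg's
## major axis is horizontal and the blunt pole points towards increasing
## column index ("right") unless stated otherwise.

#' Specification of a synthetic egg image
#'
#' @param width_px,height_px frame size in pixels.
#' @param scale pixels per mm (default 19, the standardization used for
#'   real egg photographs in this workflow).
#' @param ground_level background shell brightness in `[0, 1]`.
#' @param n_spots number of circular markings.
#' @param spot_radius_mean,spot_radius_sd marking radius distribution (mm),
#'   truncated below at 0.05 mm.
#' @param spot_darkness how much darker a marking is than the ground
#'   (`[0, 1]`).
#' @param pole_bias 0 for uniform placement; 1 for a strong linear density
#'   gradient towards the blunt pole.
#' @param overlap allow markings to overlap; if `FALSE` centres are placed
#'   with rejection sampling so discs stay disjoint.
#' @param noise_sd SD of additive Gaussian pixel noise inside the mask.
#' @param seed integer seed.
#' @return object of class `egg_image_spec`.
#' @export
egg_image_spec <- function(width_px = 380, height_px = 266, scale = 19,
                           ground_level = 0.75, n_spots = 40,
                           spot_radius_mean = 0.5, spot_radius_sd = 0.15,
                           spot_darkness = 0.45, pole_bias = 0,
                           overlap = TRUE, noise_sd = 0, seed = 1L) {
  stop_if(ground_level < 0 || ground_level > 1, "ground_level must be in [0,1]")
  stop_if(spot_darkness < 0 || spot_darkness > 1, "spot_darkness must be in [0,1]")
  stop_if(spot_radius_mean <= 0, "spot radii must be positive")
  stop_if(pole_bias < 0 || pole_bias > 1, "pole_bias must be in [0,1]")
  stop_if(scale <= 0, "scale must be positive")
  stop_if(!is_count(n_spots), "n_spots must be a count")
  structure(as.list(environment()), class = "egg_image_spec")
}

#' Egg image container
#'
#' @param pixels numeric matrix in `[0, 1]`; values outside the mask may be
#'   `NA` (flagged invalid).
#' @param mask logical matrix, `TRUE` inside the egg.
#' @param scale pixels per mm.
#' @param blunt_pole `"right"` or `"left"`: which end of the horizontal
#'   major axis is the blunt pole.
#' @return object of class `egg_image`.
#' @export
egg_image <- function(pixels, mask, scale, blunt_pole = "right") {
  stop_if(!is.matrix(pixels) || !is.matrix(mask) ||
            !all(dim(pixels) == dim(mask)), "pixels/mask must be matrices of equal size")
  mask <- mask & !is.na(mask)
  stop_if(sum(mask) == 0, "egg mask is empty")
  stop_if(any(!is.finite(pixels[mask])), "pixels must be finite inside the mask")
  stop_if(scale <= 0, "scale must be positive")
  blunt_pole <- match.arg(blunt_pole, c("right", "left"))
  structure(list(pixels = pixels, mask = mask, scale = scale,
                 blunt_pole = blunt_pole), class = "egg_image")
}

#' @export
print.egg_image <- function(x, ...) {
  cat(sprintf("<egg_image> %d x %d px, %.3g px/mm, mask %d px, blunt pole %s\n",
              nrow(x$pixels), ncol(x$pixels), x$scale, sum(x$mask),
              x$blunt_pole))
  invisible(x)
}

ellipse_mask <- function(height_px, width_px) {
  cy <- (height_px + 1) / 2
  cx <- (width_px + 1) / 2
  b <- height_px / 2 - 1
  a <- width_px / 2 - 1
  row <- matrix(seq_len(height_px), height_px, width_px)
  col <- matrix(seq_len(width_px), height_px, width_px, byrow = TRUE)
  ((col - cx) / a)^2 + ((row - cy) / b)^2 <= 1
}

#' Generate a synthetic egg image
#'
#' Draws an elliptical egg (mask inscribed in the frame) at the requested
#' ground brightness and places `n_spots` darker discs inside the mask,
#' clipped to it. With `pole_bias > 0` spot density rises linearly along
#' the major axis towards the blunt pole. Pixels outside the mask are `NA`
#' (invalid). Deterministic given the spec's seed.
#'
#' @param spec an [egg_image_spec()].
#' @return an [egg_image()].
#' @export
generate_egg_image <- function(spec) {
  stopifnot(inherits(spec, "egg_image_spec"))
  set.seed(spec$seed)
  h <- spec$height_px; w <- spec$width_px
  mask <- ellipse_mask(h, w)
  minor_semi_mm <- (h / 2 - 1) / spec$scale
  stop_if(spec$spot_radius_mean > 2 * minor_semi_mm,
          "spot radius (%.2f mm) exceeds the egg's minor axis", spec$spot_radius_mean)
  pix <- matrix(NA_real_, h, w)
  pix[mask] <- spec$ground_level
  if (spec$n_spots > 0) {
    radii_mm <- pmax(rnorm(spec$n_spots, spec$spot_radius_mean,
                           spec$spot_radius_sd), 0.05)
    radii_px <- radii_mm * spec$scale
    centres <- place_spots(mask, spec$n_spots, radii_px, spec$pole_bias,
                           spec$overlap)
    row <- matrix(seq_len(h), h, w)
    col <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (i in seq_len(spec$n_spots)) {
      disc <- (row - centres[i, 1])^2 + (col - centres[i, 2])^2 <=
        radii_px[i]^2
      pix[disc & mask] <- pmax(spec$ground_level - spec$spot_darkness, 0)
    }
  }
  if (spec$noise_sd > 0)
    pix[mask] <- pmin(pmax(pix[mask] + rnorm(sum(mask), 0, spec$noise_sd), 0), 1)
  egg_image(pix, mask, spec$scale, blunt_pole = "right")
}

## Sample spot centres inside the mask with a linear density gradient along
## the major axis (towards increasing column = blunt pole).
place_spots <- function(mask, n, radii_px, pole_bias, overlap,
                        max_tries = 20000L) {
  idx <- which(mask, arr.ind = TRUE)
  xr <- range(idx[, 2])
  centres <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    stop_if(tries > max_tries,
            "could not place %d non-overlapping spots (placed %d)", n, placed)
    cand <- idx[sample.int(nrow(idx), 1L), ]
    t <- (cand[2] - xr[1]) / max(xr[2] - xr[1], 1)
    w <- (1 - pole_bias) + pole_bias * 2 * t  # linear gradient, mean 1
    if (runif(1) > w / max(1, 2 * pole_bias + (1 - pole_bias))) next
    if (!overlap && placed > 0) {
      d <- sqrt((centres[seq_len(placed), 1] - cand[1])^2 +
                  (centres[seq_len(placed), 2] - cand[2])^2)
      if (any(d < radii_px[seq_len(placed)] + radii_px[placed + 1L] + 2)) next
    }
    placed <- placed + 1L
    centres[placed, ] <- cand
  }
  centres
}
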