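## Multi-scale feature (marking) detection: difference-of-Gaussian blob
## detection on the inverted egg image, the image-analysis analogue of
## SIFT keypoint counting used to count individual markings.

#' Detect pattern features (markings) in an egg image
#'
#' Difference-of-Gaussian blob detection over a geometric scale pyramid
#' (three scales per octave). The image is inverted (markings are dark on
#' a paler ground, so become bright blobs), filled with the in-mask mean
#' outside the mask, and blurred at sigma levels spanning the requested
#' marking-radius range. Candidate features are local maxima of the DoG
#' response over position and scale, above `threshold`, with centres
#' inside the mask; overlapping weaker candidates are suppressed. Each
#' feature's area is estimated from its detection scale
#' (`radius = sqrt(2) * sigma`). Immaculate images return zero features
#' and a missing mean feature size, which is why mean feature size is
#' excluded from the multidimensional distance.
#'
#' @param img an [egg_image()].
#' @param min_radius_mm,max_radius_mm marking radius range searched (mm).
#' @param threshold minimum DoG response (brightness units) for a feature.
#' @param scales_per_octave scale sampling density.
#' @return list with `n_features`, `mean_feature_size_mm2` (`NA` when no
#'   features) and a data frame `features` (row, col, radius_px,
#'   area_mm2, response).
#' @export
detect_features <- function(img, min_radius_mm = 0.15, max_radius_mm = 3,
                            threshold = 0.02, scales_per_octave = 3) {
  stopifnot(inherits(img, "egg_image"))
  stop_if(min_radius_mm <= 0 || max_radius_mm <= min_radius_mm,
          "need 0 < min_radius_mm < max_radius_mm")
  fill <- mean(img$pixels[img$mask])
  inv <- fill - img$pixels          # markings become positive bumps
  inv[!img$mask | is.na(inv)] <- 0
  step <- 2^(1 / scales_per_octave)
  sig_min <- min_radius_mm * img$scale / sqrt(2)
  sig_max <- max_radius_mm * img$scale / sqrt(2)
  n_lev <- ceiling(log(sig_max / sig_min) / log(step)) + 2L
  sigmas <- sig_min * step^(0:(n_lev - 1L))
  blurs <- lapply(sigmas, function(s) gblur_capped(inv, s))
  cand <- list()
  for (k in seq_len(n_lev - 1L)) {
    resp <- blurs[[k]] - blurs[[k + 1L]]   # positive at bright blob centres
    if (k == 1L) resp_lo <- NULL else resp_lo <- blurs[[k - 1L]] - blurs[[k]]
    if (k == n_lev - 1L) resp_hi <- NULL else
      resp_hi <- blurs[[k + 1L]] - blurs[[k + 2L]]
    mx <- local_max_3x3(resp)
    ok <- mx & resp > threshold & img$mask
    if (!is.null(resp_lo)) ok <- ok & resp >= resp_lo
    if (!is.null(resp_hi)) ok <- ok & resp >= resp_hi
    if (any(ok)) {
      ij <- which(ok, arr.ind = TRUE)
      sig_geo <- sigmas[k] * sqrt(step)  # geometric centre of the DoG pair
      cand[[length(cand) + 1L]] <- data.frame(
        row = ij[, 1], col = ij[, 2], sigma = sig_geo,
        radius_px = sqrt(2) * sig_geo,
        response = resp[ok])
    }
  }
  if (length(cand) == 0) {
    return(list(n_features = 0L, mean_feature_size_mm2 = NA_real_,
                features = data.frame()))
  }
  feats <- do.call(rbind, cand)
  feats <- feats[order(-feats$response), ]
  keep <- rep(TRUE, nrow(feats))
  for (i in seq_len(nrow(feats))) {
    if (!keep[i]) next
    if (i < nrow(feats)) {
      j <- (i + 1L):nrow(feats)
      d <- sqrt((feats$row[j] - feats$row[i])^2 +
                  (feats$col[j] - feats$col[i])^2)
      keep[j][d < 0.9 * (feats$radius_px[j] + feats$radius_px[i])] <- FALSE
    }
  }
  feats <- feats[keep, , drop = FALSE]
  feats$area_mm2 <- pi * (feats$radius_px / img$scale)^2
  list(n_features = nrow(feats),
       mean_feature_size_mm2 = mean(feats$area_mm2),
       features = feats[, c("row", "col", "radius_px", "area_mm2",
                            "response")])
}

## Gaussian blur with the kernel capped at the image size (large sigmas on
## small frames); the default EBImage kernel radius is 2*ceil(3*sigma)+1.
gblur_capped <- function(m, sigma) {
  r <- 2 * ceiling(3 * sigma) + 1
  lim <- min(dim(m)) - 1
  if (lim %% 2 == 0) lim <- lim - 1
  EBImage::gblur(m, sigma = sigma, radius = min(r, lim))
}

## TRUE where a pixel is the strict-or-equal maximum of its 3x3 neighbourhood.
local_max_3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  out <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out & m >= pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  out
}
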