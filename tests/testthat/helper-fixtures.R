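# Shared fixtures and independent oracles used across the suite.

# cone_catches from bare numbers
make_catches <- function(...) {
  v <- list(...)
  structure(v, class = "cone_catches")
}

# raw-unit (identity) distance standardization over the 5 pattern traits
raw_std <- function() {
  tab <- data.frame(prop_pattern = c(0, 1), dispersion = c(1, 2),
                    total_energy = c(0, 1), sd_energy = c(0, 1),
                    n_features = c(0, 1))
  fit_distance_standardization(tab, mode = "raw")
}

# one egg's worth of the 5 distance traits
egg_traits <- function(prop = 0.1, disp = 1, total = 1, sde = 0.5, nf = 10) {
  list(prop_pattern = prop, dispersion = disp, total_energy = total,
       sd_energy = sde, n_features = nf)
}

# small population for fast pipeline-level tests
small_population <- function(seed = 1) {
  generate_population(population_config(n_females_host = 60,
                                        n_females_parasite = 15,
                                        seed = seed))
}

# brute-force leave-one-out LDA oracle: equal priors, pooled covariance,
# assign to the class with the smaller Mahalanobis distance
loo_lda_oracle <- function(x, labels) {
  x <- as.matrix(x)
  labels <- factor(labels)
  assigned <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    xt <- x[-i, , drop = FALSE]
    lt <- droplevels(labels[-i])
    sw <- 0
    for (lv in levels(lt)) {
      xi <- xt[lt == lv, , drop = FALSE]
      sw <- sw + crossprod(scale(xi, center = TRUE, scale = FALSE))
    }
    sw <- sw / (nrow(xt) - nlevels(lt))
    d2 <- vapply(levels(lt), function(lv)
      mahalanobis(x[i, , drop = FALSE],
                  colMeans(xt[lt == lv, , drop = FALSE]), sw), numeric(1))
    assigned[i] <- levels(lt)[which.min(d2)]
  }
  assigned
}

# draw dark discs onto an egg image at given centres (row, col) and radius px
paint_discs <- function(img, centres, radius_px, darkness = 0.4) {
  pix <- img$pixels
  row <- matrix(seq_len(nrow(pix)), nrow(pix), ncol(pix))
  col <- matrix(seq_len(ncol(pix)), nrow(pix), ncol(pix), byrow = TRUE)
  for (i in seq_len(nrow(centres))) {
    disc <- (row - centres[i, 1])^2 + (col - centres[i, 2])^2 <= radius_px^2
    pix[disc & img$mask] <- pix[disc & img$mask] - darkness
  }
  egg_image(pix, img$mask, img$scale, img$blunt_pole)
}
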