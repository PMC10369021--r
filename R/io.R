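## Readers and writers for the package's plain-text interchange formats:
## phenotype tables, long-format reflectance spectra, and egg images with
## masks.

PHENOTYPE_REQUIRED <- c("species", "female_id", "clutch_id", "egg_id",
                        "morph", "length_mm", "width_mm", "shape_ratio",
                        "prop_pattern", "dispersion", "total_energy",
                        "sd_energy", "n_features", "mean_feature_size_mm2",
                        "catch_uv", "catch_sw", "catch_mw", "catch_lw",
                        "catch_dbl")

#' Read and validate a phenotype table CSV
#'
#' @param path CSV with the phenotype-table schema (see
#'   [generate_population()]); extra columns are kept.
#' @return validated data frame.
#' @export
read_phenotype_table <- function(path) {
  stop_if(!file.exists(path), "no such file: %s", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  validate_phenotype_table(tab)
  tab
}

validate_phenotype_table <- function(tab) {
  miss <- setdiff(PHENOTYPE_REQUIRED, names(tab))
  stop_if(length(miss) > 0, "phenotype table lacks columns: %s",
          paste(miss, collapse = ", "))
  num_cols <- setdiff(PHENOTYPE_REQUIRED,
                      c("species", "female_id", "clutch_id", "egg_id",
                        "morph"))
  for (cc in num_cols) {
    bad <- which(!is.na(tab[[cc]]) & !is.finite(suppressWarnings(
      as.numeric(tab[[cc]]))))
    stop_if(length(bad) > 0, "column %s has non-numeric values (row %d)",
            cc, bad[1])
  }
  bad_prop <- which(!is.na(tab$prop_pattern) &
                      (tab$prop_pattern < 0 | tab$prop_pattern > 1))
  stop_if(length(bad_prop) > 0,
          "prop_pattern outside [0,1] (row %d)", bad_prop[1])
  bad_nf <- which(!is.na(tab$n_features) & tab$n_features < 0)
  stop_if(length(bad_nf) > 0, "negative n_features (row %d)", bad_nf[1])
  invisible(tab)
}

#' Write a phenotype table CSV
#' @param table phenotype table.
#' @param path output path.
#' @export
write_phenotype_table <- function(table, path) {
  validate_phenotype_table(table)
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read reflectance spectra from CSV
#'
#' Accepts long format (`egg_id`, `wavelength_nm`, `reflectance`) or wide
#' format (`wavelength_nm` plus one column per egg). Wavelength grids must
#' be strictly increasing; violations are reported with the offending row.
#'
#' @param path CSV path.
#' @return named list of [reflectance_spectrum()] objects.
#' @export
read_spectra <- function(path) {
  stop_if(!file.exists(path), "no such file: %s", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  stop_if(!"wavelength_nm" %in% names(tab),
          "spectra file needs a wavelength_nm column")
  if (all(c("egg_id", "reflectance") %in% names(tab))) {
    split_tab <- split(tab, tab$egg_id)
    return(lapply(split_tab, function(s) {
      s <- s[order(s$wavelength_nm), , drop = FALSE]
      check_monotone(s$wavelength_nm, path)
      reflectance_spectrum(s$wavelength_nm, s$reflectance, id = s$egg_id[1])
    }))
  }
  check_monotone(tab$wavelength_nm, path)
  cols <- setdiff(names(tab), "wavelength_nm")
  stop_if(length(cols) == 0, "no reflectance columns in %s", path)
  setNames(lapply(cols, function(cc)
    reflectance_spectrum(tab$wavelength_nm, tab[[cc]], id = cc)), cols)
}

check_monotone <- function(wl, path) {
  bad <- which(diff(wl) <= 0)
  stop_if(length(bad) > 0,
          "wavelength grid not strictly increasing in %s (row %d)",
          path, bad[1] + 1)
}

#' Write spectra to long-format CSV
#' @param spectra named list of [reflectance_spectrum()].
#' @param path output path.
#' @export
write_spectra <- function(spectra, path) {
  long <- do.call(rbind, lapply(names(spectra), function(nm) {
    s <- spectra[[nm]]
    data.frame(egg_id = nm, wavelength_nm = s$wavelengths,
               reflectance = s$reflectance)
  }))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read an egg image (with optional mask) from PNG or TIFF
#'
#' Images are read with EBImage and converted to a grayscale `[0, 1]`
#' matrix (RGB images are averaged). If no mask file is given, the default
#' mask is the ellipse inscribed in the frame (with a warning), matching
#' the convention that photographs are cropped to the egg.
#'
#' @param path image path (PNG or TIFF, 8- or 16-bit).
#' @param mask_path optional mask image (non-zero = inside egg).
#' @param scale pixels per mm (default 19).
#' @param blunt_pole `"right"` or `"left"`.
#' @return an [egg_image()].
#' @export
read_egg_image <- function(path, mask_path = NULL, scale = 19,
                           blunt_pole = "right") {
  stop_if(!file.exists(path), "no such file: %s", path)
  pix <- as_gray_matrix(EBImage::readImage(path))
  if (is.null(mask_path)) {
    warning("no mask supplied; using the inscribed ellipse as egg mask")
    mask <- ellipse_mask(nrow(pix), ncol(pix))
  } else {
    stop_if(!file.exists(mask_path), "no such file: %s", mask_path)
    mask <- as_gray_matrix(EBImage::readImage(mask_path)) > 0.5
  }
  egg_image(pix, mask, scale, blunt_pole)
}

## EBImage stores images x-then-y; transpose into the package's
## [row, column] convention with origin top-left.
as_gray_matrix <- function(img) {
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3])], c(1, 2), mean)
  t(a)
}

#' Write an egg image (and mask) as PNG
#' @param img an [egg_image()].
#' @param path output PNG path for the pixels (NA outside mask written as
#'   0).
#' @param mask_path optional output PNG path for the mask.
#' @export
write_egg_image <- function(img, path, mask_path = NULL) {
  stopifnot(inherits(img, "egg_image"))
  pix <- img$pixels
  pix[is.na(pix)] <- 0
  EBImage::writeImage(EBImage::Image(t(pix)), path)
  if (!is.null(mask_path))
    EBImage::writeImage(EBImage::Image(t(img$mask * 1)), mask_path)
  invisible(path)
}
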