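## Statistical comparison of host and parasite phenotype distributions:
## rank tests, clutch repeatability, collinearity screening, jack-knifed
## discriminant analysis and its confusion-matrix exact test.

#' Wilcoxon rank-sum comparison of a trait between two samples
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test. The exact null
#' distribution is enumerated for small samples without ties
#' (`n1 * n2 <= 400`); otherwise the tie-corrected normal approximation is
#' used.
#'
#' @param x,y numeric samples (non-empty; `NA` dropped).
#' @return list with `W` (rank-sum statistic), `p`, and `method`.
#' @export
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stop_if(length(x) == 0 || length(y) == 0, "both samples must be non-empty")
  if (length(unique(c(x, y))) == 1) {
    warning("all values tied; p = 1")
    return(list(W = length(x) * length(y) / 2, p = 1, method = "degenerate"))
  }
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && length(x) * length(y) <= 400
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  list(W = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' One-way repeatability (intraclass correlation) of a trait
#'
#' ICC from a one-way ANOVA across groups (females/clutches):
#' `(MSB - MSW) / (MSB + (k0 - 1) * MSW)` with `k0` the standard
#' unbalanced-design mean group size correction
#' `k0 = (N - sum(n_i^2) / N) / (G - 1)`. The p value is the one-way
#' ANOVA F test of between-group differences.
#'
#' @param values numeric trait values.
#' @param groups group labels (same length).
#' @return object of class `repeatability_result`: `icc`, `F`, `p`,
#'   `n_groups`, `mean_group_size`.
#' @export
icc <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  ni <- table(groups)
  stop_if(nlevels(groups) < 2, "need at least 2 groups")
  stop_if(all(ni < 2), "need at least one group with 2+ members")
  n <- length(values); g <- nlevels(groups)
  gm <- tapply(values, groups, mean)
  ssb <- sum(ni * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  msb <- ssb / (g - 1)
  msw <- ssw / (n - g)
  k0 <- (n - sum(ni^2) / n) / (g - 1)
  icc_val <- if (msw == 0 && msb == 0) NA_real_ else
    (msb - msw) / (msb + (k0 - 1) * msw)
  f <- if (msw == 0) Inf else msb / msw
  structure(list(icc = icc_val, F = f,
                 p = pf(f, g - 1, n - g, lower.tail = FALSE),
                 n_groups = g, mean_group_size = n / g),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("ICC = %.3f (F = %.3g, p = %.3g; %d groups, mean size %.2f)\n",
              x$icc, x$F, x$p, x$n_groups, x$mean_group_size))
  invisible(x)
}

#' Greedy collinearity screen
#'
#' While any pair of traits has `|r| >= threshold`, drops the trait with
#' the highest mean absolute correlation to all remaining traits (ties
#' broken alphabetically). Deterministic.
#'
#' @param traits data frame or matrix of numeric traits.
#' @param threshold absolute-correlation cutoff (default 0.7, i.e. retained
#'   traits are not strongly collinear, r < 0.7).
#' @return character vector of retained trait names.
#' @export
collinearity_screen <- function(traits, threshold = 0.7) {
  x <- as.data.frame(traits)
  stop_if(ncol(x) < 2, "need at least 2 traits")
  keep <- sort(names(x))
  repeat {
    r <- abs(cor(x[, keep, drop = FALSE], use = "pairwise.complete.obs"))
    diag(r) <- 0
    if (all(r < threshold) || length(keep) == 1) break
    worst <- keep[order(-rowMeans(r), keep)][1]
    keep <- setdiff(keep, worst)
  }
  keep
}

#' Jack-knifed linear discriminant analysis of species assignment
#'
#' Linear discriminant analysis with equal (uninformative) priors and
#' leave-one-out (jack-knifed) class predictions, so accuracy is not
#' inflated by resubstitution or unequal sample sizes. Optionally removes
#' multivariate outliers first (Mahalanobis distance from the own-class
#' mean using the pooled within-class covariance, chi-square cutoff).
#' Perfect phenotypic overlap between species drives the per-class correct
#' rates to chance (0.5).
#'
#' @param features data frame or matrix of numeric features.
#' @param labels two-level class labels.
#' @param outlier_filter remove Mahalanobis outliers first (default FALSE).
#' @param outlier_quantile chi-square quantile for the cutoff (default
#'   0.999).
#' @return object of class `discriminant_result`: `confusion` (true x
#'   assigned), `correct_rates` per class, `coefficients` (LD1 scaling of
#'   the full-data fit), `outliers_removed` (row indices), `n`.
#' @export
lda_jackknife <- function(features, labels, outlier_filter = FALSE,
                          outlier_quantile = 0.999) {
  x <- as.matrix(features)
  labels <- factor(labels)
  stop_if(nlevels(labels) < 2, "need at least 2 classes")
  stop_if(nrow(x) <= ncol(x) + 2, "need n > features + 2")
  removed <- integer(0)
  if (outlier_filter) {
    sw <- pooled_within_cov(x, labels)
    cut <- qchisq(outlier_quantile, df = ncol(x))
    d2 <- numeric(nrow(x))
    for (lv in levels(labels)) {
      i <- labels == lv
      d2[i] <- mahalanobis(x[i, , drop = FALSE], colMeans(x[i, , drop = FALSE]), sw)
    }
    removed <- which(d2 > cut)
    if (length(removed) > 0) {
      x <- x[-removed, , drop = FALSE]
      labels <- droplevels(labels[-removed])
    }
  }
  prior <- rep(1 / nlevels(labels), nlevels(labels))
  cv <- MASS::lda(x, grouping = labels, prior = prior, CV = TRUE)
  fit <- MASS::lda(x, grouping = labels, prior = prior)
  confusion <- table(true = labels, assigned = cv$class)
  rates <- diag(prop.table(confusion, 1))
  structure(list(confusion = confusion,
                 correct_rates = rates,
                 coefficients = fit$scaling,
                 outliers_removed = removed,
                 n = nrow(x)),
            class = "discriminant_result")
}

pooled_within_cov <- function(x, labels) {
  sw <- 0
  for (lv in levels(labels)) {
    xi <- x[labels == lv, , drop = FALSE]
    sw <- sw + crossprod(scale(xi, center = TRUE, scale = FALSE))
  }
  sw / (nrow(x) - nlevels(labels))
}

#' @export
print.discriminant_result <- function(x, ...) {
  cat("<discriminant_result> n =", x$n, "\n")
  print(x$confusion)
  cat("correct rates:",
      paste(sprintf("%s %.1f%%", names(x$correct_rates),
                    100 * x$correct_rates), collapse = ", "), "\n")
  if (length(x$outliers_removed))
    cat("outliers removed:", length(x$outliers_removed), "\n")
  invisible(x)
}

#' Fisher's exact test of a discriminant confusion matrix
#'
#' Tests whether a 2x2 confusion matrix (true species x assigned species)
#' performs better than chance: two-sided Fisher's exact test by
#' hypergeometric enumeration, with the conditional-MLE odds ratio.
#'
#' @param confusion 2x2 table or matrix of non-negative integer counts.
#' @return list with `odds_ratio` (NA when a margin is empty), `p`.
#' @export
confusion_exact_test <- function(confusion) {
  m <- as.matrix(confusion)
  stop_if(!all(dim(m) == 2), "confusion matrix must be 2x2")
  stop_if(any(m < 0) || any(m != round(m)), "counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(odds_ratio = NA_real_, p = 1))
  }
  ft <- fisher.test(m)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Convenience k-means morph labelling
#'
#' k-means (`stats::kmeans`, 25 restarts, seeded) on z-scored traits. A
#' labelling convenience for simulated or field tables; the real morph
#' boundaries are soft, so these labels are indicative clusters, not a
#' validated morph classification.
#'
#' @param traits data frame or matrix of complete numeric traits.
#' @param k number of clusters (default 4).
#' @param seed RNG seed for the restarts.
#' @return integer vector of cluster labels (1..k).
#' @export
morph_cluster <- function(traits, k = 4, seed = 1L) {
  x <- scale(as.matrix(traits))
  stop_if(any(!is.finite(x)), "traits must be complete and non-constant")
  stop_if(k > nrow(x), "k cannot exceed the number of rows")
  set.seed(as.integer(seed))
  if (k == 1) return(rep(1L, nrow(x)))
  kmeans(x, centers = k, nstart = 25)$cluster
}
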