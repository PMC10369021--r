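## Binomial models of host egg rejection: individual-trait-difference
## models versus the multidimensional pattern distance model, with AIC /
## likelihood-ratio comparison, variance-function adjusted R-squared, VIF
## multicollinearity checks, and hierarchical variance partitioning.

#' Assemble experiment records from an experiment table and phenotype table
#'
#' Joins each experiment (host clutch + experimental egg) to the traits of
#' the two eggs involved. Column prefixes `host_` and `exp_` carry the
#' trait sets needed by [build_predictors()].
#'
#' @param experiments data frame with `host_egg_id`, `experimental_egg_id`
#'   and `outcome` (0 = accepted, 1 = rejected).
#' @param table phenotype table containing both eggs of every experiment.
#' @return data frame of experiment records.
#' @export
assemble_experiment_records <- function(experiments, table) {
  need <- c("host_egg_id", "experimental_egg_id", "outcome")
  miss <- setdiff(need, names(experiments))
  stop_if(length(miss) > 0, "experiments table lacks columns: %s",
          paste(miss, collapse = ", "))
  stop_if(!all(experiments$outcome %in% c(0, 1)), "outcome must be 0/1")
  ih <- match(experiments$host_egg_id, table$egg_id)
  ie <- match(experiments$experimental_egg_id, table$egg_id)
  stop_if(anyNA(ih) || anyNA(ie), "experiment egg ids missing from the table")
  trait_cols <- setdiff(names(table),
                        c("species", "female_id", "clutch_id", "egg_id",
                          "morph"))
  host <- table[ih, trait_cols, drop = FALSE]
  names(host) <- paste0("host_", trait_cols)
  ex <- table[ie, trait_cols, drop = FALSE]
  names(ex) <- paste0("exp_", trait_cols)
  cbind(experiments[, intersect(names(experiments),
                                c("experiment_id", "host_clutch_id", need))],
        host, ex, row.names = NULL)
}

#' Build model predictors from experiment records
#'
#' * `"traits"` (model 1): absolute host-experimental differences in the
#'   composite traits pattern coverage and PC energy, and in feature
#'   number. Absolute differences are the default because rejection should
#'   respond to the magnitude of mismatch; `signed = TRUE` keeps the sign.
#' * `"distance"` (model 2): the single multidimensional pattern distance.
#' * `"plus_colour"`: the chosen base model plus the chromatic contrast
#'   (JND) between host and experimental egg ground colours.
#' * `"interactions"`: model 1 plus all two-way products.
#'
#' @param records output of [assemble_experiment_records()].
#' @param model one of `"traits"`, `"distance"`, `"plus_colour"`,
#'   `"interactions"`.
#' @param std [fit_distance_standardization()] (needed for distance-based
#'   models).
#' @param composites [fit_composites()] fit (needed for trait models).
#' @param receptors receptor set for the colour contrast; default
#'   [vs_receptor_set()].
#' @param colour_base which base model `"plus_colour"` extends
#'   (`"distance"` by default).
#' @param signed keep signed rather than absolute trait differences.
#' @return data frame with `outcome` plus the predictor columns.
#' @export
build_predictors <- function(records,
                             model = c("traits", "distance", "plus_colour",
                                       "interactions"),
                             std = NULL, composites = NULL,
                             receptors = vs_receptor_set(),
                             colour_base = "distance", signed = FALSE) {
  model <- match.arg(model)
  out <- data.frame(outcome = records$outcome)
  dif <- if (signed) identity else abs

  traits_block <- function() {
    stop_if(is.null(composites), "trait models need a composite fit")
    host <- score_composites(composites, strip_prefix(records, "host_"))
    ex <- score_composites(composites, strip_prefix(records, "exp_"))
    data.frame(
      d_pattern_coverage = dif(host$pattern_coverage - ex$pattern_coverage),
      d_pc_energy = dif(host$pc_energy - ex$pc_energy),
      d_n_features = dif(host$n_features - ex$n_features))
  }
  distance_block <- function() {
    stop_if(is.null(std), "distance models need a distance standardization")
    data.frame(distance = pattern_distance_rows(
      strip_prefix(records, "host_"), strip_prefix(records, "exp_"), std))
  }
  colour_block <- function() {
    jnd <- vapply(seq_len(nrow(records)), function(i) {
      a <- catches_from_row(records[i, ], "host_")
      b <- catches_from_row(records[i, ], "exp_")
      chromatic_jnd(a, b, receptors)
    }, numeric(1))
    data.frame(chromatic_jnd = jnd)
  }

  block <- switch(model,
    traits = traits_block(),
    distance = distance_block(),
    plus_colour = cbind(if (colour_base == "distance") distance_block()
                        else traits_block(), colour_block()),
    interactions = {
      b <- traits_block()
      nm <- names(b)
      for (i in 1:(length(nm) - 1)) for (j in (i + 1):length(nm))
        b[[paste0(nm[i], ":", nm[j])]] <- b[[nm[i]]] * b[[nm[j]]]
      b
    })
  cbind(out, block)
}

strip_prefix <- function(records, prefix) {
  cols <- grep(paste0("^", prefix), names(records), value = TRUE)
  out <- records[, cols, drop = FALSE]
  names(out) <- sub(paste0("^", prefix), "", cols)
  out
}

catches_from_row <- function(row, prefix) {
  v <- unlist(row[paste0(prefix, c("catch_uv", "catch_sw", "catch_mw",
                                   "catch_lw", "catch_dbl"))])
  structure(list(uv = unname(v[1]), sw = unname(v[2]), mw = unname(v[3]),
                 lw = unname(v[4]), dbl = unname(v[5])),
            class = "cone_catches")
}

#' Fit a binomial egg-rejection model
#'
#' Logit-link binomial GLM of rejection (1) vs acceptance (0) on the
#' predictors in `data` (all non-`outcome` columns). Reports coefficients
#' with SEs, log-likelihood, AIC, two adjusted R-squared flavours
#' (variance-function based, the default report, and McFadden), and VIFs
#' when there are 2+ predictors. Complete separation is detected (from the
#' fitted probabilities and diverging coefficients) and raised as an
#' error, since ML estimates are then unbounded; a penalized fit is the
#' appropriate remedy in that case.
#'
#' @param data data frame with `outcome` (0/1) and numeric predictors; an
#'   intercept-only model is fitted when there are no predictor columns.
#' @param model_label free-text label stored in the fit.
#' @return object of class `rejection_fit`.
#' @export
fit_rejection_glm <- function(data, model_label = "rejection model") {
  stop_if(!"outcome" %in% names(data), "data must contain `outcome`")
  y <- data$outcome
  stop_if(!all(y %in% c(0, 1)), "outcome must be 0/1")
  stop_if(length(unique(y)) < 2, "both outcome classes must be present")
  fit <- suppressWarnings(glm(outcome ~ ., data = data, family = binomial()))
  mu <- fitted(fit)
  eta <- predict(fit)
  if (length(coef(fit)) > 1 &&
      max(eta[y == 0]) < min(eta[y == 1]) &&
      (any(mu > 1 - 1e-8) || any(mu < 1e-8))) {
    stop("perfect separation detected: ML estimates diverge; ",
         "consider a penalized (Firth) fit", call. = FALSE)
  }
  sm <- summary(fit)
  n <- length(y)
  p_coef <- length(coef(fit))
  ## variance-function-based generalized R2 (Pearson-residual form) and
  ## its adjustment; McFadden's likelihood ratio R2 as labelled alternative
  mu0 <- mean(y)
  r2v <- 1 - sum((y - mu)^2 / (mu * (1 - mu))) /
    sum((y - mu0)^2 / (mu0 * (1 - mu0)))
  adj_r2 <- 1 - (1 - r2v) * (n - 1) / (n - p_coef)
  ll0 <- sum(y * log(mu0) + (1 - y) * log(1 - mu0))
  mcfadden <- 1 - as.numeric(logLik(fit)) / ll0
  preds <- setdiff(names(data), "outcome")
  vifs <- if (length(preds) >= 2)
    vif(as.matrix(data[, preds, drop = FALSE])) else NULL
  structure(list(
    glm = fit,
    coefficients = coef(fit),
    se = sm$coefficients[, "Std. Error"],
    z = sm$coefficients[, "z value"],
    p_values = sm$coefficients[, "Pr(>|z|)"],
    logLik = as.numeric(logLik(fit)),
    aic = AIC(fit),
    adj_r2 = adj_r2,
    mcfadden_r2 = mcfadden,
    vif = vifs,
    predictors = preds,
    n = n,
    label = model_label
  ), class = "rejection_fit")
}

#' @export
print.rejection_fit <- function(x, ...) {
  cat("<rejection_fit>", x$label, sprintf("(n = %d)\n", x$n))
  tab <- cbind(estimate = x$coefficients, se = x$se, p = x$p_values)
  print(round(tab, 4))
  cat(sprintf("logLik %.3f  AIC %.2f  adj R2 %.3f  (McFadden %.3f)\n",
              x$logLik, x$aic, x$adj_r2, x$mcfadden_r2))
  if (!is.null(x$vif)) cat("VIF:", paste(sprintf("%s %.2f", names(x$vif),
                                                 x$vif), collapse = ", "), "\n")
  invisible(x)
}

#' Predict rejection probabilities from a fitted model
#' @param fit a `rejection_fit`.
#' @param newdata data frame with the fit's predictor columns.
#' @return vector of probabilities in (0, 1).
#' @export
predict_rejection <- function(fit, newdata) {
  stopifnot(inherits(fit, "rejection_fit"))
  as.numeric(predict(fit$glm, newdata = newdata, type = "response"))
}

#' Compare two rejection models
#'
#' Always reports `delta_aic = AIC(a) - AIC(b)`. When one predictor set is
#' nested in the other (and both were fitted on the same number of
#' records), also reports the likelihood-ratio test of the larger against
#' the smaller model; for non-nested pairs the LRT is refused and only the
#' AIC difference is returned.
#'
#' @param fit_a,fit_b `rejection_fit` objects on the same records.
#' @return list with `delta_aic` and, when nested, `lrt`, `df`, `p`.
#' @export
compare_models <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "rejection_fit"), inherits(fit_b, "rejection_fit"))
  stop_if(fit_a$n != fit_b$n, "models were fitted on different record counts")
  out <- list(delta_aic = fit_a$aic - fit_b$aic)
  a_in_b <- all(fit_a$predictors %in% fit_b$predictors)
  b_in_a <- all(fit_b$predictors %in% fit_a$predictors)
  if (a_in_b || b_in_a) {
    big <- if (a_in_b) fit_b else fit_a
    small <- if (a_in_b) fit_a else fit_b
    lrt <- 2 * (big$logLik - small$logLik)
    df <- length(big$coefficients) - length(small$coefficients)
    out$lrt <- lrt
    out$df <- df
    out$p <- if (df > 0) pchisq(lrt, df, lower.tail = FALSE) else NA_real_
  } else {
    out$lrt <- NA_real_
    out$note <- "predictor sets not nested; LRT refused"
  }
  out
}

#' Hierarchical partitioning of variance explained between predictors
#'
#' All-subsets hierarchical partitioning (Chevan & Sutherland): every
#' subset of predictors is fitted as a binomial GLM, goodness of fit is
#' the deviance explained (null minus residual deviance), and each
#' predictor's independent contribution is the average improvement it
#' brings when added, averaged within and then across hierarchy levels.
#' Reported as percentages (`%I`) normalized to sum to 100.
#'
#' @param data data frame with `outcome` and predictor columns.
#' @param predictors predictor names (default: all non-outcome columns;
#'   at most 8, since all `2^k` subsets are fitted).
#' @return named vector of `%I` values summing to 100.
#' @export
partition_variance <- function(data, predictors = NULL) {
  predictors <- predictors %||% setdiff(names(data), "outcome")
  k <- length(predictors)
  stop_if(k < 1, "need at least one predictor")
  stop_if(k > 8, "all-subsets partitioning limited to 8 predictors")
  ## subsets as bitmasks: gof[mask + 1] is the deviance explained by the
  ## predictors whose bits are set in mask
  masks <- 0:(2^k - 1)
  gof <- numeric(length(masks))
  for (mask in masks) {
    inc <- predictors[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    f <- if (length(inc) == 0) outcome ~ 1 else
      stats::reformulate(sprintf("`%s`", inc), response = "outcome")
    m <- glm(f, data = data, family = binomial())
    stop_if(!m$converged, "subset fit did not converge: %s",
            paste(inc, collapse = "+"))
    gof[mask + 1] <- m$null.deviance - m$deviance
  }
  n_bits <- vapply(masks, function(m) sum(bitwAnd(m, 2^(seq_len(k) - 1)) > 0),
                   numeric(1))
  indep <- setNames(numeric(k), predictors)
  for (j in seq_len(k)) {
    bit <- 2^(j - 1)
    without_j <- masks[bitwAnd(masks, bit) == 0]
    gains <- gof[without_j + bit + 1] - gof[without_j + 1]
    lvl <- n_bits[without_j + 1]
    indep[j] <- mean(tapply(gains, lvl, mean))
  }
  100 * indep / sum(indep)
}

#' Variance inflation factors of a design matrix
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from the linear regression of
#' predictor `j` on all other predictors. Exact collinearity yields `Inf`.
#'
#' @param x numeric matrix or data frame of 2+ predictors.
#' @return named vector of VIFs (all >= 1).
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  stop_if(ncol(x) < 2, "VIF needs at least 2 predictors")
  vapply(seq_len(ncol(x)), function(j) {
    fit <- lm(x[, j] ~ x[, -j, drop = FALSE])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> setNames(colnames(x))
}
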