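#' Match detections to labeled boxes at an IOU threshold
#'
#' Greedy one-to-one matching: detections are visited in score-descending
#' order and each is matched to the not-yet-matched labeled box of highest
#' IOU, provided that IOU is strictly larger than the threshold (ties between
#' truth candidates broken by larger IOU). Matched pairs are true positives;
#' unmatched detections are false positives; unmatched labeled boxes are false
#' negatives.
#'
#' @param pred Detection table (already score-filtered).
#' @param truth Labeled box table.
#' @param iou_threshold Matching threshold (default 0.5, strict inequality).
#' @return A one-row tibble with `tp`, `fp`, `fn`.
#' @export
match_detections <- function(pred, truth, iou_threshold = 0.5) {
  pred <- as_tibble(pred)
  truth <- as_tibble(truth)
  if (nrow(pred) == 0 || nrow(truth) == 0) {
    return(tibble(tp = 0L, fp = nrow(pred), fn = nrow(truth)))
  }
  scores <- pred$score %||% rep(1, nrow(pred))
  ord <- order(-scores, pred$xmin, pred$ymin)
  matched_truth <- logical(nrow(truth))
  tp <- 0L
  for (i in ord) {
    ious <- iou(pred[i, ], truth)
    ious[matched_truth] <- -Inf
    j <- which.max(ious)
    if (ious[j] > iou_threshold) {
      matched_truth[j] <- TRUE
      tp <- tp + 1L
    }
  }
  tibble(tp = tp, fp = nrow(pred) - tp, fn = nrow(truth) - tp)
}

#' Detection bias from precision and recall
#'
#' A scalar summarizing the precision/recall imbalance, zero when they are
#' equal. The default convention is `1 - recall / precision`, which is
#' negative when recall exceeds precision (over-detection pulls precision
#' down, bias toward reporting too many stems gives a negative value). The
#' alternative `1 - precision / recall` convention is available via
#' `convention = "inverse"`.
#'
#' @param precision,recall Values in `(0, 1]`.
#' @param convention `"standard"` (`1 - recall/precision`, default) or
#'   `"inverse"` (`1 - precision/recall`).
#' @return Numeric bias value.
#' @examples
#' detection_bias(0.95, 0.97) # about -0.02
#' @export
detection_bias <- function(precision, recall, convention = c("standard", "inverse")) {
  convention <- match.arg(convention)
  if (any(precision <= 0) || any(recall <= 0)) {
    abort("Precision and recall must be positive to compute a bias ratio.")
  }
  switch(convention,
    standard = 1 - recall / precision,
    inverse = 1 - precision / recall
  )
}

#' Precision, recall and bias from match counts
#'
#' @param counts A one-row data frame with `tp`, `fp`, `fn` (see
#'   [match_detections()]).
#' @inheritParams detection_bias
#' @return A one-row tibble with `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `bias`.
#' @export
detection_metrics <- function(counts, convention = c("standard", "inverse")) {
  convention <- match.arg(convention)
  counts <- as_tibble(counts)
  if (counts$tp + counts$fp == 0) abort("No accepted detections: precision undefined (tp + fp = 0).")
  if (counts$tp + counts$fn == 0) abort("No labeled boxes: recall undefined (tp + fn = 0).")
  precision <- counts$tp / (counts$tp + counts$fp)
  recall <- counts$tp / (counts$tp + counts$fn)
  bias <- if (counts$tp == 0) NA_real_ else detection_bias(precision, recall, convention)
  tibble(tp = counts$tp, fp = counts$fp, fn = counts$fn,
         precision = precision, recall = recall, bias = bias)
}

#' Agreement metrics between estimated and reference values
#'
#' Ordinary least squares of the reference on the estimated values gives
#' slope, intercept and R^2; RMSE is the root mean squared difference between
#' the two series, and RRMSE expresses it as a percentage of the mean of the
#' reference values.
#'
#' @param estimated,reference Equal-length numeric vectors (n >= 3).
#' @return A one-row tibble: `n`, `slope`, `intercept`, `r2`, `rmse`, `rrmse`.
#' @export
regression_metrics <- function(estimated, reference) {
  if (length(estimated) != length(reference)) abort("Lengths differ.")
  if (length(estimated) < 3) abort("Need at least 3 pairs.")
  if (abs(mean(reference)) < .Machine$double.eps) abort("Reference mean is zero; RRMSE undefined.")
  fit <- lm(reference ~ estimated)
  tibble(
    n = length(estimated),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r2 = suppressWarnings(summary(fit)$r.squared),
    rmse = sqrt(mean((estimated - reference)^2)),
    rrmse = relative_rmse(sqrt(mean((estimated - reference)^2)), mean(reference))
  )
}

#' RMSE as a percentage of the reference mean
#'
#' @param rmse Root mean squared error, in the units of the variable.
#' @param reference_mean Mean of the reference (measured) values.
#' @return RRMSE in percent.
#' @examples
#' relative_rmse(24.45, 352) # 6.95 at 2 dp
#' @export
relative_rmse <- function(rmse, reference_mean) {
  if (any(reference_mean == 0)) abort("Reference mean is zero; RRMSE undefined.")
  100 * rmse / reference_mean
}

#' Descriptive summary of a trait vector
#'
#' @param values Numeric vector, n >= 2.
#' @return One-row tibble: `n`, `min`, `mean`, `max`, `range`, `sd`, `cv`
#'   (percent, computed as `100 * sd / mean` with the n-1 standard deviation).
#' @export
summarize_values <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) abort("Need at least 2 finite values.")
  tibble(
    n = length(values),
    min = min(values),
    mean = mean(values),
    max = max(values),
    range = max(values) - min(values),
    sd = sd(values),
    cv = 100 * sd(values) / mean(values)
  )
}

#' Leave-one-out cross-validated linear regression
#'
#' For each observation, a linear model is fitted on all remaining
#' observations and used to predict the held-out response. Metrics are
#' computed over the pooled out-of-fold predictions: R^2 from ordinary least
#' squares of the observed on the predicted values, RMSE of the predictions,
#' and RRMSE relative to the mean observed response.
#'
#' @param data Data frame of predictors and response.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor column names (one for a
#'   single-trait model, several for the joint multiple regression).
#' @return An object of class `loocv_fit` with `predictions` (tibble of
#'   `observed`, `predicted`), `metrics` (one-row tibble `r2`, `rmse`,
#'   `rrmse`), `response`, `predictors`, `n`.
#' @export
loocv_regression <- function(data, response, predictors) {
  data <- as_tibble(data)
  if (!response %in% names(data)) abort(paste0("No column `", response, "`."))
  miss <- setdiff(predictors, names(data))
  if (length(miss) > 0) abort(paste0("Missing predictor(s): ", paste(miss, collapse = ", "), "."))
  df <- data[, c(response, predictors)]
  df <- df[stats::complete.cases(df), ]
  n <- nrow(df)
  if (n < 5) abort("Need at least 5 complete observations.")
  X <- as.matrix(df[, predictors, drop = FALSE])
  if (qr(cbind(1, X))$rank < length(predictors) + 1) {
    abort("Rank-deficient predictor table.")
  }
  fml <- stats::as.formula(paste(response, "~", paste(predictors, collapse = " + ")))
  pred <- vapply(seq_len(n), function(i) {
    fit <- lm(fml, data = df[-i, ])
    unname(predict(fit, newdata = df[i, ]))
  }, numeric(1))
  obs <- df[[response]]
  rmse <- sqrt(mean((pred - obs)^2))
  metrics <- tibble(
    r2 = suppressWarnings(summary(lm(obs ~ pred))$r.squared),
    rmse = rmse,
    rrmse = relative_rmse(rmse, mean(obs))
  )
  structure(
    list(predictions = tibble(observed = obs, predicted = pred),
         metrics = metrics, response = response, predictors = predictors, n = n),
    class = "loocv_fit"
  )
}

#' @export
print.loocv_fit <- function(x, ...) {
  cat("Leave-one-out cross-validated model: ", x$response, " ~ ",
      paste(x$predictors, collapse = " + "), "  (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  R2 = %.3f, RMSE = %.3g, RRMSE = %.2f%%\n",
              x$metrics$r2, x$metrics$rmse, x$metrics$rrmse))
  invisible(x)
}

#' @export
tidy.loocv_fit <- function(x, ...) x$predictions

#' @export
glance.loocv_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble(response = x$response,
           model = paste(x$predictors, collapse = " + "),
           n = x$n),
    x$metrics
  )
}

#' @export
autoplot.loocv_fit <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = paste0("predicted ", object$response, " (leave-one-out)"),
      y = paste0("observed ", object$response),
      title = sprintf("R2 = %.2f, RRMSE = %.1f%%",
                      object$metrics$r2, object$metrics$rrmse)
    ) +
    ggplot2::theme_minimal()
}

#' Broad-sense heritability from a replicated trial
#'
#' One-way random-effects decomposition over genotypes: the residual variance
#' Ve is the within-genotype mean square; the genotypic variance Vg is
#' `(between MS - within MS) / r` with `r` the harmonic mean of the replicate
#' counts (robust to unbalanced replication), clipped at zero. Heritability is
#' `H2 = Vg / (Vg + Ve)`, the repeatability of a single-plot observation.
#'
#' @param genotype Vector of genotype identifiers, one per plot.
#' @param value Trait value per plot.
#' @return An object of class `heritability_fit` with `vg`, `ve`, `h2`,
#'   `n_genotypes`, `n_plots`, `harmonic_reps`.
#' @export
heritability <- function(genotype, value) {
  keep <- is.finite(value) & !is.na(genotype)
  genotype <- factor(genotype[keep])
  value <- value[keep]
  if (nlevels(genotype) < 2) abort("Need at least 2 genotypes.")
  reps <- table(genotype)
  if (all(reps < 2)) abort("Need replicates for at least some genotypes.")
  ms <- suppressWarnings(anova(aov(value ~ genotype)))
  ms_between <- ms$`Mean Sq`[1]
  ms_within <- ms$`Mean Sq`[2]
  r_bar <- nlevels(genotype) / sum(1 / as.numeric(reps))
  vg <- max((ms_between - ms_within) / r_bar, 0)
  ve <- ms_within
  structure(
    list(vg = vg, ve = ve, h2 = vg / (vg + ve),
         n_genotypes = nlevels(genotype), n_plots = length(value),
         harmonic_reps = r_bar),
    class = "heritability_fit"
  )
}

#' @export
print.heritability_fit <- function(x, ...) {
  cat(sprintf(
    "Broad-sense heritability: H2 = %.3f (Vg = %.3g, Ve = %.3g; %d genotypes, %d plots)\n",
    x$h2, x$vg, x$ve, x$n_genotypes, x$n_plots))
  invisible(x)
}

#' @export
tidy.heritability_fit <- function(x, ...) {
  tibble(term = c("vg", "ve", "h2"), estimate = c(x$vg, x$ve, x$h2))
}

#' @export
glance.heritability_fit <- function(x, ...) {
  tibble(vg = x$vg, ve = x$ve, h2 = x$h2,
         n_genotypes = x$n_genotypes, n_plots = x$n_plots,
         harmonic_reps = x$harmonic_reps)
}
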