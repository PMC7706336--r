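#' Sampled ground area of a plot
#'
#' Field sampling takes `n_samples` samples of `rows_per_sample` crop rows by
#' `length` metres, with rows spaced `row_spacing` metres apart; the sampled
#' area is the product of the four. Three samples of two rows by 1.0 m at
#' 0.17 m row spacing give the conventional 1.02 m^2.
#'
#' @param n_samples Number of samples per plot.
#' @param rows_per_sample Crop rows per sample.
#' @param row_spacing Row spacing in metres (default 0.17).
#' @param length Sample length along the row in metres.
#' @return Sampled area in m^2.
#' @examples
#' sampled_area(3, 2, 0.17, 1.0) # 1.02
#' @export
sampled_area <- function(n_samples, rows_per_sample, row_spacing = 0.17, length = 1.0) {
  if (any(c(n_samples, rows_per_sample, row_spacing, length) <= 0)) {
    abort("All sampling dimensions must be positive.")
  }
  n_samples * rows_per_sample * row_spacing * length
}

#' Stem density
#'
#' Number of stems counted over a plot's image extracts divided by the
#' sampled ground area.
#'
#' @param count Number of stems (>= 0).
#' @param area Sampled area in m^2 (> 0).
#' @return Density in stems/m^2.
#' @export
stem_density <- function(count, area) {
  if (any(area <= 0)) abort("`area` must be positive.")
  if (any(count < 0)) abort("`count` must be non-negative.")
  count / area
}

#' Mean of a gamma distribution
#'
#' @param shape,scale Gamma parameters (> 0).
#' @return `shape * scale`.
#' @export
gamma_mean <- function(shape, scale) {
  if (any(shape <= 0) || any(scale <= 0)) abort("Gamma parameters must be positive.")
  shape * scale
}

#' Fit gamma and normal distributions to stem diameters
#'
#' Per-plot stem diameters are fitted by maximum likelihood to both a gamma
#' and a normal distribution, each assessed by a one-sample Kolmogorov-Smirnov
#' test against the fitted law. The identical procedure on both families makes
#' the p-value comparison like-for-like (the optimism of KS with estimated
#' parameters cancels), and the family with the larger p-value is selected.
#'
#' @param diameters Numeric vector of diameters in mm; at least 10 finite
#'   positive values.
#' @return An object of class `diameter_fit` with components `gamma`
#'   (`shape`, `scale`, `p_value`), `normal` (`mean`, `sd`, `p_value`),
#'   `selected` (`"gamma"` or `"normal"`), `n`, and the data.
#' @export
fit_diameter_distribution <- function(diameters) {
  d <- diameters[is.finite(diameters)]
  if (length(d) < 10) abort("Need at least 10 finite diameters.")
  if (any(d <= 0)) abort("Diameters must be positive for the gamma fit.")
  if (sd(d) < .Machine$double.eps^0.5) abort("Degenerate (constant) diameters.")
  m <- mean(d); v <- var(d)
  gfit <- suppressWarnings(fitdistrplus::fitdist(d, "gamma"))
  shape <- unname(gfit$estimate["shape"])
  scale <- 1 / unname(gfit$estimate["rate"])
  p_gamma <- suppressWarnings(
    ks.test(d, "pgamma", shape = shape, rate = 1 / scale)$p.value
  )
  p_normal <- suppressWarnings(
    ks.test(d, "pnorm", mean = m, sd = sd(d))$p.value
  )
  structure(
    list(
      gamma = list(shape = shape, scale = scale, p_value = p_gamma),
      normal = list(mean = m, sd = sd(d), p_value = p_normal),
      selected = if (p_gamma >= p_normal) "gamma" else "normal",
      n = length(d),
      diameters = d
    ),
    class = "diameter_fit"
  )
}

#' @export
print.diameter_fit <- function(x, ...) {
  cat("Stem diameter distribution fit (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  gamma : shape %.3f scale %.3f (mean %.3f mm), KS p = %.3g\n",
              x$gamma$shape, x$gamma$scale, gamma_mean(x$gamma$shape, x$gamma$scale),
              x$gamma$p_value))
  cat(sprintf("  normal: mean %.3f sd %.3f, KS p = %.3g\n",
              x$normal$mean, x$normal$sd, x$normal$p_value))
  cat("  selected family:", x$selected, "\n")
  invisible(x)
}

#' @export
tidy.diameter_fit <- function(x, ...) {
  tibble(
    family = c("gamma", "gamma", "normal", "normal"),
    term = c("shape", "scale", "mean", "sd"),
    estimate = c(x$gamma$shape, x$gamma$scale, x$normal$mean, x$normal$sd)
  )
}

#' @export
glance.diameter_fit <- function(x, ...) {
  tibble(
    n = x$n,
    shape = x$gamma$shape,
    scale = x$gamma$scale,
    mean_gamma = gamma_mean(x$gamma$shape, x$gamma$scale),
    p_gamma = x$gamma$p_value,
    p_normal = x$normal$p_value,
    selected = x$selected
  )
}

#' @export
autoplot.diameter_fit <- function(object, bins = 30, ...) {
  df <- tibble(diameter = object$diameters)
  grid <- tibble(diameter = seq(min(df$diameter), max(df$diameter), length.out = 200))
  grid <- tidyr::expand_grid(grid, family = c("gamma", "normal"))
  grid$density <- ifelse(
    grid$family == "gamma",
    dgamma(grid$diameter, shape = object$gamma$shape, scale = object$gamma$scale),
    dnorm(grid$diameter, mean = object$normal$mean, sd = object$normal$sd)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diameter)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$density, colour = .data$family)) +
    ggplot2::labs(x = "stem diameter (mm)", y = "density",
                  colour = "fitted family",
                  title = paste0("Selected: ", object$selected)) +
    ggplot2::theme_minimal()
}

#' Basal area of a plot
#'
#' Mean cross-section area of the measured stems (each `pi * (d/2)^2`, with
#' the diameter in metres) multiplied by the stem density. Using the mean of
#' per-stem areas (not the area of the mean diameter) keeps the statistic
#' sensitive to the diameter spread.
#'
#' @param diameters_mm Valid per-stem diameters in mm (>= 1 value).
#' @param density Stem density in stems/m^2 (>= 0).
#' @return Basal area in m^2 of stem section per m^2 of ground.
#' @export
basal_area <- function(diameters_mm, density) {
  d <- diameters_mm[is.finite(diameters_mm)]
  if (length(d) == 0) abort("No valid stem diameters.")
  if (any(density < 0)) abort("`density` must be non-negative.")
  mean(pi * (d / 2000)^2) * density
}

#' Biovolume of a plot
#'
#' Basal area times plant height: a structural proxy for above-ground
#' biomass.
#'
#' @param basal Basal area in m^2/m^2 (>= 0).
#' @param height Plant height in metres (>= 0).
#' @return Biovolume in m^3/m^2.
#' @export
biovolume <- function(basal, height) {
  if (any(basal < 0) || any(height < 0)) abort("Inputs must be non-negative.")
  basal * height
}

#' Plot-level traits from per-stem measurements
#'
#' Aggregates a per-stem measurement table (see [measure_stems()]) into one
#' row of plot traits: stem density, mean diameter, diameter-distribution fit
#' (when at least 10 valid stems are available), basal area, and biovolume
#' (when a height is supplied).
#'
#' @param measurements Per-stem measurement table for one plot.
#' @param area Sampled ground area in m^2.
#' @param height Plant height in metres, or `NA` to skip biovolume.
#' @param plot_id Optional plot identifier carried into the output.
#' @return One-row tibble: `plot_id`, `n_stems`, `n_measured`,
#'   `sampled_area_m2`, `stem_density`, `mean_diameter_mm`, `dist_family`,
#'   `shape`, `scale`, `p_gamma`, `p_normal`, `height_m`, `basal_area`,
#'   `biovolume`.
#' @export
plot_traits <- function(measurements, area, height = NA_real_, plot_id = NA_character_) {
  measurements <- as_tibble(measurements)
  n <- nrow(measurements)
  density <- stem_density(n, area)
  d <- measurements$diameter_mm[measurements$valid %||% rep(TRUE, n)]
  d <- d[is.finite(d)]
  fit <- if (length(d) >= 10) {
    tryCatch(fit_diameter_distribution(d), error = function(e) NULL)
  }
  ba <- if (length(d) > 0) basal_area(d, density) else NA_real_
  tibble(
    plot_id = plot_id,
    n_stems = n,
    n_measured = length(d),
    sampled_area_m2 = area,
    stem_density = density,
    mean_diameter_mm = if (length(d) > 0) mean(d) else NA_real_,
    dist_family = if (!is.null(fit)) fit$selected else NA_character_,
    shape = if (!is.null(fit)) fit$gamma$shape else NA_real_,
    scale = if (!is.null(fit)) fit$gamma$scale else NA_real_,
    p_gamma = if (!is.null(fit)) fit$gamma$p_value else NA_real_,
    p_normal = if (!is.null(fit)) fit$normal$p_value else NA_real_,
    height_m = height,
    basal_area = ba,
    biovolume = if (is.finite(height) && is.finite(ba)) biovolume(ba, height) else NA_real_
  )
}
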