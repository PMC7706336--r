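#' Specification of a synthetic stubble scene
#'
#' Describes a nadir view of cut stems after combine harvest: bright
#' ring-shaped cross sections placed along crop rows over a darker soil
#' background, at a known ground resolution. Defaults mirror the acquisition
#' and crop conditions the package targets: 0.12-0.18 mm/px ground
#' resolution, rows 0.17 m apart, stem diameters gamma-distributed with
#' shape 6 and scale 0.35 mm (mean 2.1 mm), densities of a few hundred
#' stems/m^2.
#'
#' @param width_px,height_px Image size in pixels.
#' @param resolution_mm Ground resolution in mm/pixel (default 0.18).
#' @param row_spacing_m Crop row spacing in metres (default 0.17).
#' @param density Stem density in stems/m^2 (default 500).
#' @param shape,scale Gamma parameters of the stem diameter law in mm
#'   (default 6 and 0.35).
#' @param min_diameter_mm Physical lower truncation of the diameter law in mm
#'   (default 1.0); the sub-millimetre gamma tail is resampled since cut
#'   cereal stems that thin do not occur.
#' @param background Mean background gray level (default 60).
#' @param contrast Peak ring intensity above background (default 120).
#' @param lumen_lift Gray-level lift of the stem lumen above background
#'   (default 12), so the inside of the ring is slightly brighter than soil
#'   but darker than the wall.
#' @param ring_sigma_px Radial Gaussian width of the rendered stem wall in px
#'   (default 1.2).
#' @param blur_sigma_px Optical blur applied to the whole scene, in px
#'   (default 0.8).
#' @param noise_sigma Gaussian gray-level noise sigma (default 0 = clean).
#' @param n_straw Number of bright straw streaks of clutter (default 0).
#' @param occluded_fraction Fraction of stems covered by straw and therefore
#'   undetectable (default 0).
#' @param seed Integer seed fixing the scene exactly.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(width_px = 1000, height_px = 950,
                       resolution_mm = 0.18, row_spacing_m = 0.17,
                       density = 500, shape = 6, scale = 0.35,
                       min_diameter_mm = 1.0,
                       background = 60, contrast = 120, lumen_lift = 12,
                       ring_sigma_px = 1.2, blur_sigma_px = 0.8,
                       noise_sigma = 0, n_straw = 0,
                       occluded_fraction = 0, seed = 1L) {
  if (occluded_fraction < 0 || occluded_fraction >= 1) {
    abort("`occluded_fraction` must be in [0, 1).")
  }
  structure(as.list(environment()), class = "scene_spec")
}

# Separable Gaussian blur with edge replication.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  kern <- dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  blur1 <- function(x) {
    n <- nrow(x)
    pad <- x[pmin(pmax(seq(1 - half, n + half), 1), n), , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (s in seq_along(kern)) {
      out <- out + kern[s] * pad[(s - 1) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(m))))
}

local_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Render a synthetic stubble scene with exact ground truth
#'
#' Stems are placed along rows with jitter and a minimum center separation
#' (jittered regular slots, so packing is deterministic per seed); each stem
#' is drawn as a Gaussian-profiled bright annulus at its ring-center radius
#' over a slightly lifted lumen; optional straw streaks and Gaussian noise
#' are added and the scene is blurred. The stem count equals
#' `round(density * footprint area)`, so the pipeline can be scored against
#' an exactly known density.
#'
#' @param spec A [scene_spec()].
#' @return A list of class `stem_scene`: `image` (`height x width x 3` RGB
#'   array, `[0, 255]`), `truth` (tibble with per-stem `x`, `y`,
#'   `radius_px`, `diameter_px`, `diameter_mm`, `xmin`..`ymax` ground-truth
#'   box, `occluded`), `area_m2`, and the `spec`.
#' @export
render_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))
  W <- spec$width_px; H <- spec$height_px
  res <- spec$resolution_mm
  area_m2 <- W * H * res^2 / 1e6
  n <- round(spec$density * area_m2)
  if (n < 1) abort("Expected stem count < 1; enlarge the scene or the density.")

  # truncated gamma: resample the sub-millimetre tail (~0.4% of draws), which
  # has no physical counterpart in cut cereal stems and is unresolvable at
  # 0.12-0.18 mm/px anyway
  d_mm <- rgamma(n, shape = spec$shape, scale = spec$scale)
  for (it in 1:50) {
    low <- d_mm < spec$min_diameter_mm
    if (!any(low)) break
    d_mm[low] <- rgamma(sum(low), shape = spec$shape, scale = spec$scale)
  }
  d_mm <- pmax(d_mm, spec$min_diameter_mm)
  r_px <- d_mm / 2 / res

  row_gap_px <- spec$row_spacing_m * 1000 / res
  n_rows <- max(1L, round(H / row_gap_px))
  row_y <- (seq_len(n_rows) - 0.5) * H / n_rows
  row_of <- rep(seq_len(n_rows), length.out = n)
  margin <- 1.25 * max(r_px) + 3
  min_sep <- 2.4 * max(r_px)

  xs <- numeric(n); ys <- numeric(n)
  for (rw in seq_len(n_rows)) {
    idx <- which(row_of == rw)
    ni <- length(idx)
    if (ni == 0) next
    usable <- W - 2 * margin
    slot <- usable / ni
    if (slot < min_sep) {
      abort("Infeasible stem density for this scene geometry (packing failure).")
    }
    centers <- margin + (seq_len(ni) - 0.5) * slot
    jit <- (slot - min_sep) / 2
    xs[idx] <- centers + runif(ni, -jit, jit)
    ys[idx] <- row_y[rw] + runif(ni, -3, 3)
  }
  ys <- pmin(pmax(ys, margin), H - margin)

  occluded <- rep(FALSE, n)
  if (spec$occluded_fraction > 0) {
    occluded[sample.int(n, round(spec$occluded_fraction * n))] <- TRUE
  }

  img <- matrix(spec$background, H, W)
  for (i in seq_len(n)) {
    half <- ceiling(r_px[i] + 4 * spec$ring_sigma_px)
    ci <- round(ys[i]); cj <- round(xs[i])
    rows <- max(1, ci - half):min(H, ci + half)
    cols <- max(1, cj - half):min(W, cj + half)
    # pixel (row a, col b) has continuous center (b - 0.5, a - 0.5)
    dy <- (rows - 0.5) - ys[i]
    dx <- (cols - 0.5) - xs[i]
    rr <- sqrt(outer(dy^2, dx^2, "+"))
    bump <- spec$contrast * exp(-(rr - r_px[i])^2 / (2 * spec$ring_sigma_px^2)) +
      spec$lumen_lift * (rr < r_px[i])
    img[rows, cols] <- img[rows, cols] + bump
  }

  straw_targets <- which(occluded)
  n_streaks <- spec$n_straw + length(straw_targets)
  if (n_streaks > 0) {
    for (s in seq_len(n_streaks)) {
      if (s <= length(straw_targets)) {
        i <- straw_targets[s]
        x0 <- xs[i]; y0 <- ys[i]
        len <- 6 * r_px[i]
        wdt <- 2.5 * r_px[i]     # wide enough to bury the ring
      } else {
        x0 <- runif(1, 0, W); y0 <- runif(1, 0, H)
        len <- runif(1, 40, 160)
        wdt <- runif(1, 2, 5)
      }
      th <- runif(1, 0, pi)
      ux <- cos(th); uy <- sin(th)
      half <- ceiling(len / 2 + wdt + 2)
      rows <- max(1, round(y0) - half):min(H, round(y0) + half)
      cols <- max(1, round(x0) - half):min(W, round(x0) + half)
      dy <- (rows - 0.5) - y0
      dx <- (cols - 0.5) - x0
      along <- outer(dy * uy, dx * ux, "+")
      ortho2 <- outer(dy^2, dx^2, "+") - along^2
      mask <- (abs(along) <= len / 2) & (ortho2 <= (wdt / 2)^2)
      img[rows, cols] <- pmax(img[rows, cols],
                              spec$background + 0.75 * spec$contrast * mask)
    }
  }

  img <- gaussian_blur(img, spec$blur_sigma_px)
  if (spec$noise_sigma > 0) {
    img <- img + matrix(rnorm(H * W, 0, spec$noise_sigma), H, W)
  }
  img <- pmin(pmax(img, 0), 255)
  rgb <- array(0, c(H, W, 3))
  rgb[, , 1] <- pmin(img * 1.04, 255)    # straw-tinted: slightly warm
  rgb[, , 2] <- img
  rgb[, , 3] <- img * 0.82

  box_half <- 1.25 * r_px
  truth <- tibble(
    stem = seq_len(n),
    x = xs, y = ys,
    radius_px = r_px,
    diameter_px = 2 * r_px,
    diameter_mm = d_mm,
    xmin = xs - box_half, ymin = ys - box_half,
    xmax = xs + box_half, ymax = ys + box_half,
    occluded = occluded
  )
  structure(list(image = rgb, truth = truth, area_m2 = area_m2, spec = spec),
            class = "stem_scene")
}

#' @export
print.stem_scene <- function(x, ...) {
  cat(sprintf(
    "Synthetic stubble scene: %d x %d px at %.2f mm/px (%.4f m^2), %d stems (%d occluded)\n",
    x$spec$width_px, x$spec$height_px, x$spec$resolution_mm, x$area_m2,
    nrow(x$truth), sum(x$truth$occluded)))
  invisible(x)
}

#' @export
autoplot.stem_scene <- function(object, detections = NULL, ...) {
  gray <- rgb_to_gray(object$image)
  df <- tidyr::expand_grid(y = seq_len(nrow(gray)), x = seq_len(ncol(gray)))
  df$value <- as.vector(t(gray))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::geom_rect(
      data = object$truth,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax),
      inherit.aes = FALSE, fill = NA, colour = "green3", linewidth = 0.3
    ) +
    ggplot2::theme_void()
  if (!is.null(detections)) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(detections),
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax),
      inherit.aes = FALSE, fill = NA, colour = "yellow", linewidth = 0.3
    )
  }
  p
}

#' Specification of a synthetic replicated trial
#'
#' Describes a genotype trial in the package's trait space: each plot value is
#' `mean + g + e` with a genotypic effect `g ~ N(0, vg)` shared by the
#' genotype's replicates and a residual `e ~ N(0, ve)` per plot, so the
#' designed plot-level broad-sense heritability per trait is `vg/(vg+ve)`.
#' Above-ground biomass is proportional to biovolume up to multiplicative
#' noise, and ear density equals stem density up to a small zero-mean
#' discrepancy. Defaults mirror a 16-genotype wheat trial replicated 6-15
#' times with heritability 0.8 for every trait.
#'
#' @param n_genotypes Number of genotypes (default 16).
#' @param reps_range Integer range of replicates per genotype (default 6:15).
#' @param means Named vector: trait means (`density` stems/m^2, `diameter`
#'   mm, `height` m).
#' @param h2 Designed heritability per trait (recycled; default 0.8).
#' @param total_sd Named vector of total (genotypic + residual) standard
#'   deviations per trait.
#' @param beta_agb AGB per unit biovolume, g/m^2 per m^3/m^2 (default 8.5e5,
#'   giving AGB near 1000 g/m^2 at typical trait values).
#' @param agb_noise_cv Multiplicative noise on AGB (default 0.06).
#' @param ear_density_sd SD of the ear-vs-stem density discrepancy
#'   (default 15 stems/m^2).
#' @param seed Integer seed.
#' @return A list of class `trial_spec`.
#' @export
trial_spec <- function(n_genotypes = 16, reps_range = c(6L, 15L),
                       means = c(density = 550, diameter = 2.1, height = 0.75),
                       h2 = 0.8,
                       total_sd = c(density = 115, diameter = 0.15, height = 0.08),
                       beta_agb = 8.5e5, agb_noise_cv = 0.06,
                       ear_density_sd = 15, seed = 1L) {
  if (n_genotypes < 2) abort("Need at least 2 genotypes.")
  h2 <- rep_len(h2, 3)
  names(h2) <- c("density", "diameter", "height")
  structure(as.list(environment()), class = "trial_spec")
}

#' Generate a synthetic replicated trial table
#'
#' @param spec A [trial_spec()].
#' @return A tibble with one row per plot: `plot_id`, `genotype`,
#'   `stem_density`, `mean_diameter_mm`, `height_m`, `basal_area`,
#'   `biovolume`, `ear_density`, `agb`. The designed heritabilities are
#'   attached as attribute `designed_h2`.
#' @export
generate_trial <- function(spec = trial_spec()) {
  stopifnot(inherits(spec, "trial_spec"))
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))
  reps <- sample(seq(spec$reps_range[1], spec$reps_range[2]),
                 spec$n_genotypes, replace = TRUE)
  genotype <- rep(sprintf("G%02d", seq_len(spec$n_genotypes)), times = reps)
  n <- length(genotype)

  draw_trait <- function(trait) {
    vt <- spec$total_sd[[trait]]^2
    vg <- spec$h2[[trait]] * vt
    ve <- vt - vg
    g <- rnorm(spec$n_genotypes, 0, sqrt(vg))
    spec$means[[trait]] + rep(g, times = reps) + rnorm(n, 0, sqrt(ve))
  }
  density <- pmax(draw_trait("density"), 10)
  diameter <- pmax(draw_trait("diameter"), 0.5)
  height <- pmax(draw_trait("height"), 0.1)

  basal <- pi * (diameter / 2000)^2 * density
  biovol <- basal * height
  agb <- spec$beta_agb * biovol * (1 + rnorm(n, 0, spec$agb_noise_cv))
  ear <- density + rnorm(n, 0, spec$ear_density_sd)

  out <- tibble(
    plot_id = sprintf("P%03d", seq_len(n)),
    genotype = genotype,
    stem_density = density,
    mean_diameter_mm = diameter,
    height_m = height,
    basal_area = basal,
    biovolume = biovol,
    ear_density = ear,
    agb = agb
  )
  attr(out, "designed_h2") <- spec$h2
  out
}
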