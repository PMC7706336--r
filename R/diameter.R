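#' Convert 8-bit RGB values to gray levels
#'
#' The fixed linear combination `V = 0.2989 R + 0.5870 G + 0.1140 B`, applied
#' without rounding. Stem cross sections are identified by relative pixel
#' brightness, so all downstream measurement operates on this single channel.
#'
#' @param r,g,b Numeric vectors of channel values in `[0, 255]`.
#' @return Numeric vector of gray levels in `[0, 255)`.
#' @examples
#' to_gray(255, 255, 255) # 254.9745
#' @export
to_gray <- function(r, g, b) {
  chk <- c(r, g, b)
  if (any(chk < 0 | chk > 255)) abort("Channel values must lie in [0, 255].")
  0.2989 * r + 0.5870 * g + 0.1140 * b
}

#' Convert an RGB image array to a gray matrix
#'
#' @param img `height x width x 3` array on the `[0, 255]` scale, or an
#'   already-gray matrix (returned unchanged).
#' @return `height x width` gray matrix.
#' @export
rgb_to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) != 3 || dim(img)[3] < 3) {
    abort("Expected a height x width x 3 array.")
  }
  to_gray(img[, , 1], img[, , 2], img[, , 3])
}

# Bilinear interpolation of a gray matrix at continuous (x, y) positions.
# Pixel (i, j) (0-based col, row) covers [i, i+1) x [j, j+1); its center is
# (i + 0.5, j + 0.5). Samples are clamped to the outermost pixel centers.
bilinear_sample <- function(gray, x, y) {
  w <- ncol(gray)
  h <- nrow(gray)
  gx <- pmin(pmax(x - 0.5, 0), w - 1)
  gy <- pmin(pmax(y - 0.5, 0), h - 1)
  x0 <- pmin(floor(gx), w - 2)
  y0 <- pmin(floor(gy), h - 2)
  fx <- gx - x0
  fy <- gy - y0
  i00 <- cbind(y0 + 1, x0 + 1)
  i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1)
  i11 <- cbind(y0 + 2, x0 + 2)
  gray[i00] * (1 - fx) * (1 - fy) + gray[i01] * fx * (1 - fy) +
    gray[i10] * (1 - fx) * fy + gray[i11] * fx * fy
}

#' Extract gray-value profiles along four compass directions
#'
#' Profiles pass through the box center along 0, 45, 90 and 135 degrees,
#' sampled by bilinear interpolation every 0.5 px and clipped to the box.
#' Positions are reported relative to the center (negative on one side,
#' positive on the other), so a centered circular stem produces two symmetric
#' intensity maxima per profile where the line crosses the bright stem wall.
#'
#' @param gray Gray matrix of the full image (see [rgb_to_gray()]).
#' @param box A single box in image coordinates (see [as_boxes()]).
#' @param step Sampling step along the line, in pixels (default 0.5).
#' @return A tibble with columns `direction` (degrees), `position` (px,
#'   signed distance from the center along the line) and `value` (gray level).
#' @export
extract_profiles <- function(gray, box, step = 0.5) {
  box <- as_boxes(box)
  if (nrow(box) != 1) abort("`box` must be a single box.")
  if (box$xmax - box$xmin < 4 || box$ymax - box$ymin < 4) {
    abort("Box smaller than 4x4 px: profile too short to measure.")
  }
  cx <- (box$xmin + box$xmax) / 2
  cy <- (box$ymin + box$ymax) / 2
  purrr::map_dfr(c(0, 45, 90, 135), function(theta) {
    dx <- cos(theta * pi / 180)
    dy <- sin(theta * pi / 180)
    tx <- if (abs(dx) > 1e-12) (box$xmax - cx) / abs(dx) else Inf
    ty <- if (abs(dy) > 1e-12) (box$ymax - cy) / abs(dy) else Inf
    tmax <- min(tx, ty)
    k <- floor(tmax / step)
    t <- step * seq(-k, k)
    tibble(
      direction = theta,
      position = t,
      value = bilinear_sample(gray, cx + t * dx, cy + t * dy)
    )
  })
}

# Discrete Gaussian smoothing of a profile (sigma in samples); reflective ends.
smooth_profile <- function(v, sigma) {
  if (sigma <= 0) return(v)
  half <- max(1L, ceiling(3 * sigma))
  kern <- dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  n <- length(v)
  idx <- c(rev(seq_len(half) + 1L), seq_len(n), n - seq_len(half))
  padded <- v[pmin(pmax(idx, 1L), n)]
  stats::filter(padded, kern, sides = 2)[half + seq_len(n)]
}

# Peak position on one side of a profile with parabolic sub-sample refinement.
# `side_idx` indexes into the full profile; returns NA when the maximum sits at
# the profile end (truncated stem border) or the side is flat (no border).
side_peak <- function(position, value, side_idx, toward_center_last) {
  v <- value[side_idx]
  if (length(v) < 5) return(NA_real_)
  if (diff(range(v)) < .Machine$double.eps^0.5) return(NA_real_)
  m <- max(v)
  ties <- which(v >= m - .Machine$double.eps^0.5 * max(1, abs(m)))
  # tie-break toward the box center
  j <- if (toward_center_last) ties[length(ties)] else ties[1]
  if (j == 1 || j == length(v)) return(NA_real_)
  i <- side_idx[j]
  y1 <- value[i - 1]; y2 <- value[i]; y3 <- value[i + 1]
  denom <- y1 - 2 * y2 + y3
  offset <- if (abs(denom) < .Machine$double.eps) 0 else 0.5 * (y1 - y3) / denom
  offset <- min(max(offset, -0.5), 0.5)
  step <- position[2] - position[1]
  position[i] + offset * step
}

#' Stem diameter from a single gray-value profile
#'
#' The two borders of a stem appear as the two maximum gray values of the
#' profile, one on each side of the box center. The returned diameter is the
#' separation of the two maxima, refined to sub-sample precision by parabolic
#' interpolation over the three samples around each peak. The measurement is
#' invalid (NA) when either maximum lies at a profile endpoint (border
#' truncated by the box) or either side is flat.
#'
#' @param position Signed positions along the line (px), center at 0.
#' @param value Gray values at those positions.
#' @return Diameter in pixels, or `NA_real_` when invalid.
#' @export
diameter_from_profile <- function(position, value) {
  ord <- order(position)
  position <- position[ord]
  value <- value[ord]
  left <- which(position < 0)
  right <- which(position > 0)
  if (length(left) < 5 || length(right) < 5) {
    abort("Profile needs at least 5 samples on each side of the center.")
  }
  p_left <- side_peak(position, value, left, toward_center_last = TRUE)
  p_right <- side_peak(position, value, right, toward_center_last = FALSE)
  if (is.na(p_left) || is.na(p_right)) return(NA_real_)
  p_right - p_left
}

#' Measure one stem's diameter from its detection box
#'
#' Extracts the four compass profiles, measures the max-to-max distance in
#' each, and averages the valid directions. A measurement is valid when at
#' least two directions produced a diameter and the mean lies strictly between
#' 0 and the box diagonal.
#'
#' @param gray Gray matrix of the full image.
#' @param det One detection row (box + score).
#' @param resolution Ground resolution in mm/pixel.
#' @param smooth_sigma Optional Gaussian smoothing of each profile, in samples
#'   (default 0 = none); useful on noisy imagery.
#' @return A one-row tibble: `d0`, `d45`, `d90`, `d135` (px), `n_valid`,
#'   `mean_px`, `diameter_mm`, `valid`.
#' @export
measure_stem <- function(gray, det, resolution, smooth_sigma = 0) {
  if (resolution <= 0) abort("`resolution` must be positive (mm/pixel).")
  profs <- extract_profiles(gray, det)
  per_dir <- vapply(c(0, 45, 90, 135), function(theta) {
    p <- profs[profs$direction == theta, ]
    v <- smooth_profile(p$value, smooth_sigma)
    tryCatch(diameter_from_profile(p$position, v), error = function(e) NA_real_)
  }, numeric(1))
  n_valid <- sum(!is.na(per_dir))
  mean_px <- if (n_valid > 0) mean(per_dir, na.rm = TRUE) else NA_real_
  det <- as_boxes(det)
  diag_px <- sqrt((det$xmax - det$xmin)^2 + (det$ymax - det$ymin)^2)
  valid <- n_valid >= 2 && !is.na(mean_px) && mean_px > 0 && mean_px < diag_px
  tibble(
    d0 = per_dir[1], d45 = per_dir[2], d90 = per_dir[3], d135 = per_dir[4],
    n_valid = n_valid,
    mean_px = mean_px,
    diameter_mm = mean_px * resolution,
    valid = valid
  )
}

#' Measure diameters for a table of detections
#'
#' Applies [measure_stem()] to every detection and binds the results to the
#' detection columns, producing the per-stem measurement table written by the
#' pipeline (`plot_id`, `image_id`, box, `score`, per-direction and mean
#' diameters, `valid`).
#'
#' @param gray Gray matrix of the full image.
#' @param dets Detection table in image coordinates.
#' @inheritParams measure_stem
#' @return A tibble with one row per detection.
#' @export
measure_stems <- function(gray, dets, resolution, smooth_sigma = 0) {
  dets <- as_tibble(dets)
  if (nrow(dets) == 0) {
    return(dplyr::bind_cols(dets, tibble(
      d0 = numeric(0), d45 = numeric(0), d90 = numeric(0), d135 = numeric(0),
      n_valid = integer(0), mean_px = numeric(0), diameter_mm = numeric(0),
      valid = logical(0)
    )))
  }
  res <- purrr::map_dfr(seq_len(nrow(dets)), function(i) {
    measure_stem(gray, dets[i, ], resolution, smooth_sigma)
  })
  dplyr::bind_cols(dets, res)
}
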