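#' Detector configuration
#'
#' Parameters of the annulus-template detector. Stem cross sections appear as
#' bright rings of roughly known radius (diameter near 2 mm divided by the
#' ground resolution), so the search is restricted to a radius interval.
#'
#' @param radius_min,radius_max Ring-center radius search range in pixels.
#' @param score_floor Minimum detector score in `[0, 1]` for a candidate to be
#'   emitted (default 0.7, i.e. a normalized correlation of 0.4 — low enough
#'   to expose the sub-threshold score distribution, high enough to reject
#'   partial-arc responses; the pipeline applies the final 0.80 cut).
#' @param nms_iou IOU at or above which two candidates are considered the same
#'   object during non-maximum suppression (default 0.2).
#' @param ring_sigma Radial width (Gaussian sigma, px) of the ring template
#'   (default 1.5).
#' @param radius_ratio Ratio between consecutive radii of the searched
#'   geometric grid (default 1.22, so the best-matching template radius is
#'   always within about 10% of the true ring radius).
#' @param margin Box margin around the detected radius as a fraction of the
#'   radius (default 0.25), so diameter profiles see background on both sides.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(radius_min = 2.5, radius_max = 12, score_floor = 0.7,
                            nms_iou = 0.2, ring_sigma = 1.5,
                            radius_ratio = 1.22, margin = 0.25) {
  if (radius_min <= 0 || radius_max < radius_min) {
    abort("Need 0 < radius_min <= radius_max.")
  }
  if (radius_ratio <= 1) abort("`radius_ratio` must exceed 1.")
  structure(
    list(radius_min = radius_min, radius_max = radius_max,
         score_floor = score_floor, nms_iou = nms_iou,
         ring_sigma = ring_sigma, radius_ratio = radius_ratio, margin = margin),
    class = "detector_config"
  )
}

# Zero-mean annulus template: radial Gaussian ridge at `radius`, sigma
# `ring_sigma`, over an odd square support wide enough to include background.
ring_template <- function(radius, ring_sigma = 1.5) {
  half <- ceiling(radius + 3 * ring_sigma)
  ax <- seq(-half, half)
  r <- sqrt(outer(ax^2, ax^2, "+"))
  t <- exp(-(r - radius)^2 / (2 * ring_sigma^2))
  t - mean(t)
}

# Zero-mean normalized cross-correlation of `gray` with an odd-sized,
# zero-mean template. Returns a matrix the size of `gray` with the correlation
# at each center where the template fits entirely inside the image, and -Inf
# elsewhere. FFT for the numerator, integral images for the local moments.
# `pad`/`fft_img` let callers reuse one padded image FFT across templates.
zncc_map <- function(gray, template, pad = NULL, fft_img = NULL) {
  k <- nrow(template)
  h <- (k - 1) %/% 2
  H <- nrow(gray); W <- ncol(gray)
  if (k > H || k > W) abort("Template larger than the image.")
  if (is.null(pad)) {
    pad <- c(stats::nextn(H + k - 1, c(2, 3, 5)), stats::nextn(W + k - 1, c(2, 3, 5)))
  }
  P <- pad[1]; Q <- pad[2]
  if (is.null(fft_img)) {
    ip <- matrix(0, P, Q); ip[1:H, 1:W] <- gray
    fft_img <- stats::fft(ip)
  }
  tp <- matrix(0, P, Q); tp[1:k, 1:k] <- template
  xc <- Re(stats::fft(fft_img * Conj(stats::fft(tp)), inverse = TRUE)) / (P * Q)
  num <- xc[1:(H - k + 1), 1:(W - k + 1), drop = FALSE]

  # window sums of I and I^2 via integral images
  ii <- function(m) {
    ii <- apply(apply(m, 2, cumsum), 1, cumsum) # transposed cumulative sums
    t(ii)
  }
  wsum <- function(m) {
    s <- ii(m)
    s <- rbind(0, cbind(0, s))
    a <- 1:(H - k + 1); b <- 1:(W - k + 1)
    s[a + k, b + k, drop = FALSE] - s[a, b + k, drop = FALSE] -
      s[a + k, b, drop = FALSE] + s[a, b, drop = FALSE]
  }
  s1 <- wsum(gray)
  s2 <- wsum(gray^2)
  n <- k * k
  varw <- pmax(s2 - s1^2 / n, 0)
  denom <- sqrt(varw * sum(template^2))
  corr <- ifelse(denom > 1e-8, num / denom, 0)
  out <- matrix(-Inf, H, W)
  out[h + 1:(H - k + 1), h + 1:(W - k + 1)] <- corr
  out
}

# TRUE at strict-or-tied local maxima of m over a 3x3 neighbourhood.
local_maxima <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  ok <- matrix(TRUE, H, W)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ok <- ok & (m >= pad[2:(H + 1) + di, 2:(W + 1) + dj])
  }
  ok & is.finite(m)
}

#' Detect stem cross sections as bright rings
#'
#' Matched-filter detector: the gray image is correlated (zero-mean normalized
#' cross-correlation) with annulus templates over a grid of radii; local
#' correlation maxima above the score floor become candidate stems. Each
#' candidate is emitted as a square box of side `2 * radius * (1 + margin)`
#' centered on the peak, with score `(correlation + 1) / 2`, and candidates
#' are reduced by greedy non-maximum suppression at `nms_iou`. Because the
#' correlation is mean- and contrast-normalized, detections are invariant to
#' global gain and offset changes of the image.
#'
#' @param gray Gray matrix on the `[0, 255]` scale (see [rgb_to_gray()]).
#' @param cfg A [detector_config()].
#' @return Detection tibble (`xmin`, `ymin`, `xmax`, `ymax`, `score`,
#'   `radius_px`), score-descending.
#' @export
detect_rings <- function(gray, cfg = detector_config()) {
  stopifnot(inherits(cfg, "detector_config"))
  if (2 * cfg$radius_max > min(dim(gray)) / 2) {
    abort("Radius range wider than half the image; shrink radius_max or enlarge the patch.")
  }
  n_radii <- max(1, ceiling(log(cfg$radius_max / cfg$radius_min) /
                              log(cfg$radius_ratio)))
  radii <- unique(cfg$radius_min * cfg$radius_ratio^(0:n_radii))
  radii <- c(radii[radii < cfg$radius_max], cfg$radius_max)
  kmax <- nrow(ring_template(cfg$radius_max, cfg$ring_sigma))
  pad <- c(stats::nextn(nrow(gray) + kmax - 1, c(2, 3, 5)),
           stats::nextn(ncol(gray) + kmax - 1, c(2, 3, 5)))
  ip <- matrix(0, pad[1], pad[2]); ip[seq_len(nrow(gray)), seq_len(ncol(gray))] <- gray
  fft_img <- stats::fft(ip)
  best <- matrix(-Inf, nrow(gray), ncol(gray))
  best_r <- matrix(NA_real_, nrow(gray), ncol(gray))
  for (r in radii) {
    m <- zncc_map(gray, ring_template(r, cfg$ring_sigma), pad = pad, fft_img = fft_img)
    upd <- m > best
    best[upd] <- m[upd]
    best_r[upd] <- r
  }
  floor_corr <- 2 * cfg$score_floor - 1
  cand <- which(local_maxima(best) & best >= floor_corr, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(tibble(xmin = numeric(0), ymin = numeric(0), xmax = numeric(0),
                  ymax = numeric(0), score = numeric(0), radius_px = numeric(0)))
  }
  cand <- unname(cand)
  cx <- cand[, 2] - 0.5   # pixel centers in continuous 0-based coordinates
  cy <- cand[, 1] - 0.5
  r <- best_r[cand]
  half <- r * (1 + cfg$margin)
  dets <- tibble(
    xmin = cx - half, ymin = cy - half, xmax = cx + half, ymax = cy + half,
    score = (best[cand] + 1) / 2, radius_px = r
  )
  dets <- dets[order(-dets$score, dets$xmin, dets$ymin), ]
  keep <- logical(nrow(dets))
  kept <- integer(0)
  for (i in seq_len(nrow(dets))) {
    if (length(kept) == 0 || all(iou(dets[i, ], dets[kept, ]) < cfg$nms_iou)) {
      keep[i] <- TRUE
      kept <- c(kept, i)
    }
  }
  dets[keep, ]
}

#' Run the full detection pipeline on one image
#'
#' The canonical order of operations: plan a patch tiling (default 1000 px
#' patches with 50% overlap), detect rings per patch (or ingest externally
#' produced detections), translate boxes to parent-image coordinates,
#' eliminate cross-patch duplicates at an overlap fraction of 0.75, and drop
#' detections scoring below 0.80. Deterministic for fixed inputs.
#'
#' @param image RGB array or gray matrix on the `[0, 255]` scale.
#' @param detections Optional externally produced detection table in
#'   parent-image coordinates (e.g. from [read_detections()]); when supplied
#'   the in-package detector is skipped and only the post-processing runs.
#' @param cfg [detector_config()] for the in-package detector.
#' @param patch_size,overlap Tiling parameters (see [plan_tiling()]).
#' @param merge_overlap Overlap fraction for duplicate elimination
#'   (default 0.75).
#' @param score_threshold Final confidence cut (default 0.80).
#' @param filter_first If `TRUE`, apply the score cut before duplicate
#'   elimination instead of after (default `FALSE`: merge, then filter).
#' @return Detection tibble in parent-image coordinates.
#' @export
run_detection_pipeline <- function(image, detections = NULL,
                                   cfg = detector_config(),
                                   patch_size = 1000, overlap = 0.5,
                                   merge_overlap = 0.75,
                                   score_threshold = 0.80,
                                   filter_first = FALSE) {
  if (is.null(detections)) {
    gray <- rgb_to_gray(image)
    plan <- plan_tiling(ncol(gray), nrow(gray), patch_size, overlap)
    detections <- purrr::map_dfr(seq_len(nrow(plan)), function(i) {
      p <- plan[i, ]
      patch <- gray[p$y + seq_len(p$height), p$x + seq_len(p$width), drop = FALSE]
      d <- detect_rings(patch, cfg)
      d$xmin <- d$xmin + p$x; d$xmax <- d$xmax + p$x
      d$ymin <- d$ymin + p$y; d$ymax <- d$ymax + p$y
      d
    })
  } else {
    detections <- as_tibble(detections)
  }
  if (nrow(detections) == 0) return(detections)
  if (filter_first) {
    merge_across_patches(filter_by_score(detections, score_threshold), merge_overlap)
  } else {
    filter_by_score(merge_across_patches(detections, merge_overlap), score_threshold)
  }
}
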