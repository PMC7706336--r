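#' Axis-aligned boxes and detection tables
#'
#' Throughout the package a *box* is an axis-aligned rectangle in pixel
#' coordinates, 0-based and half-open: it covers `[xmin, xmax) x [ymin, ymax)`
#' with the origin at the top-left corner, x rightward and y downward. A
#' *detection table* is a tibble with at least the columns `xmin`, `ymin`,
#' `xmax`, `ymax` and `score` (confidence in `[0, 1]`); `plot_id` and
#' `image_id` columns are carried along when present.
#'
#' @param x A data frame with columns `xmin`, `ymin`, `xmax`, `ymax`, or a
#'   numeric vector of length 4 in that order.
#' @return A tibble of validated boxes.
#' @examples
#' as_boxes(c(0, 0, 10, 10))
#' @export
as_boxes <- function(x) {
  if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) != 4) {
      abort("A numeric box must have length 4: xmin, ymin, xmax, ymax.")
    }
    x <- tibble(xmin = x[1], ymin = x[2], xmax = x[3], ymax = x[4])
  }
  x <- as_tibble(x)
  need <- c("xmin", "ymin", "xmax", "ymax")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(paste0("Missing box column(s): ", paste(missing, collapse = ", "), "."))
  }
  bad <- which(!(x$xmax > x$xmin & x$ymax > x$ymin))
  if (length(bad) > 0) {
    abort(paste0(
      "Degenerate (zero- or negative-area) box at row(s) ",
      paste(head(bad, 5), collapse = ", "), "."
    ))
  }
  x
}

#' Box areas in square pixels
#'
#' @inheritParams as_boxes
#' @return Numeric vector of areas, one per box row.
#' @export
box_area <- function(x) {
  x <- as_boxes(x)
  (x$xmax - x$xmin) * (x$ymax - x$ymin)
}

intersection_area <- function(a, b) {
  w <- pmin(a$xmax, b$xmax) - pmax(a$xmin, b$xmin)
  h <- pmin(a$ymax, b$ymax) - pmax(a$ymin, b$ymin)
  pmax(w, 0) * pmax(h, 0)
}

recycle_boxes <- function(a, b) {
  a <- as_boxes(a)
  b <- as_boxes(b)
  if (nrow(a) != nrow(b)) {
    if (nrow(a) == 1) a <- a[rep(1, nrow(b)), ]
    else if (nrow(b) == 1) b <- b[rep(1, nrow(a)), ]
    else abort("Box tables must have the same number of rows (or one row).")
  }
  list(a = a, b = b)
}

#' Intersection over union of two boxes
#'
#' The standard detection-overlap measure: intersection area divided by union
#' area. Symmetric, in `[0, 1]`, and vectorised over paired rows (a one-row
#' table is recycled against the other argument).
#'
#' @param a,b Boxes (see [as_boxes()]).
#' @return Numeric vector of IOU values.
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 0, 15, 10)) # 50 / 150
#' @export
iou <- function(a, b) {
  p <- recycle_boxes(a, b)
  inter <- intersection_area(p$a, p$b)
  inter / (box_area(p$a) + box_area(p$b) - inter)
}

#' Overlap fraction of two boxes
#'
#' Intersection area divided by the smaller of the two box areas. A box nested
#' inside another scores 1 regardless of the size difference, which is exactly
#' the situation that duplicated detections from overlapping patches create;
#' this is the statistic used by [merge_across_patches()].
#'
#' @inheritParams iou
#' @return Numeric vector of overlap fractions in `[0, 1]`.
#' @examples
#' overlap_fraction(c(0, 0, 10, 10), c(5, 0, 15, 10)) # 50 / 100
#' @export
overlap_fraction <- function(a, b) {
  p <- recycle_boxes(a, b)
  inter <- intersection_area(p$a, p$b)
  inter / pmin(box_area(p$a), box_area(p$b))
}

#' Plan a patch tiling of an image
#'
#' Large images are processed in square patches with a fixed overlap between
#' neighbours so that objects cut by one patch border fall inside the interior
#' of another. Anchors advance by `stride = patch_size * (1 - overlap)`; when
#' the last regular anchor does not reach the image edge a final anchor is
#' clamped to `dim - patch_size`. Images smaller than the patch yield a single
#' patch clipped to the image (no padding, so no synthetic border content).
#'
#' @param width,height Image dimensions in pixels.
#' @param patch_size Patch side in pixels (default 1000).
#' @param overlap Fraction of overlap between neighbouring patches in
#'   `[0, 1)` (default 0.5).
#' @return A tibble with one row per patch: anchor `x`, `y` and the clipped
#'   patch `width`, `height`; rows in row-major order. `patch_size` and
#'   `stride` are attached as attributes.
#' @examples
#' plan_tiling(1500, 1000)           # anchors x = 0, 500
#' nrow(plan_tiling(6000, 4000))     # 77
#' @export
plan_tiling <- function(width, height, patch_size = 1000, overlap = 0.5) {
  if (width < 1 || height < 1) abort("Image dimensions must be >= 1 pixel.")
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1).")
  stride <- patch_size * (1 - overlap)
  axis_anchors <- function(dim) {
    if (dim <= patch_size) return(0)
    last <- dim - patch_size
    a <- seq(0, last, by = stride)
    if (a[length(a)] < last) a <- c(a, last)
    a
  }
  xs <- axis_anchors(width)
  ys <- axis_anchors(height)
  plan <- tidyr::expand_grid(y = ys, x = xs)[, c("x", "y")]
  plan$width <- pmin(patch_size, width - plan$x)
  plan$height <- pmin(patch_size, height - plan$y)
  attr(plan, "patch_size") <- patch_size
  attr(plan, "stride") <- stride
  plan
}

#' Eliminate duplicated detections across overlapping patches
#'
#' Detections coming from overlapping patches describe the same stem more than
#' once. Conflicts are resolved greedily in score-descending order (ties broken
#' by position, lexicographically on `xmin`, `ymin`, `xmax`, `ymax`): a
#' detection is kept only if its [overlap_fraction()] with every
#' previously kept detection is below `overlap_threshold`. Among every
#' conflicting pair the lower-score member is eliminated, and the operation is
#' idempotent.
#'
#' @param dets Detection table in parent-image coordinates.
#' @param overlap_threshold Overlap fraction at or above which two detections
#'   are considered the same stem (default 0.75).
#' @return The surviving detections, in score-descending order.
#' @export
merge_across_patches <- function(dets, overlap_threshold = 0.75) {
  dets <- as_tibble(dets)
  if (nrow(dets) == 0) return(dets)
  as_boxes(dets)
  ord <- order(-dets$score, dets$xmin, dets$ymin, dets$xmax, dets$ymax)
  dets <- dets[ord, ]
  keep <- logical(nrow(dets))
  kept_idx <- integer(0)
  for (i in seq_len(nrow(dets))) {
    if (length(kept_idx) == 0 ||
        all(overlap_fraction(dets[i, ], dets[kept_idx, ]) < overlap_threshold)) {
      keep[i] <- TRUE
      kept_idx <- c(kept_idx, i)
    }
  }
  dets[keep, ]
}

#' Filter detections by confidence score
#'
#' Detections with a confidence score below the threshold are not considered
#' stems. The threshold is inclusive: a score exactly at the threshold is kept.
#'
#' @param dets Detection table with a `score` column.
#' @param threshold Minimum confidence score (default 0.80).
#' @return The detections with `score >= threshold`, input order preserved.
#' @export
filter_by_score <- function(dets, threshold = 0.80) {
  dets <- as_tibble(dets)
  if (nrow(dets) == 0) return(dets)
  if (is.null(dets$score)) abort("Detection table has no `score` column.")
  dets[dets$score >= threshold, ]
}
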