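# Shared fixtures: tiny rendered objects and independent brute-force oracles.

# Render a single centered annulus with the same radial model as the scene
# generator: background + Gaussian ring ridge at radius R + lifted lumen.
make_annulus <- function(R, size = 2 * ceiling(2.5 * R) + 9, ring_sigma = 1.2,
                         blur = 1, background = 60, contrast = 120,
                         lumen = 12, cx = size / 2, cy = size / 2) {
  ax <- seq_len(size) - 0.5
  rr <- sqrt(outer((ax - cy)^2, (ax - cx)^2, "+"))
  img <- background + contrast * exp(-(rr - R)^2 / (2 * ring_sigma^2)) +
    lumen * (rr < R)
  stemscan:::gaussian_blur(img, blur)
}

# Integer-pixel brute-force overlap oracle for boxes with integer corners:
# counts unit cells in the intersection and in each box.
pixel_overlap_oracle <- function(a, b) {
  cells <- function(box) {
    if (box$xmax <= box$xmin || box$ymax <= box$ymin) return(NULL)
    expand.grid(x = seq(box$xmin, box$xmax - 1), y = seq(box$ymin, box$ymax - 1))
  }
  ca <- cells(a); cb <- cells(b)
  key <- function(d) paste(d$x, d$y)
  inter <- length(intersect(key(ca), key(cb)))
  list(
    iou = inter / (nrow(ca) + nrow(cb) - inter),
    overlap_fraction = inter / min(nrow(ca), nrow(cb))
  )
}

# Random integer-corner box within a bounded canvas.
random_int_box <- function(canvas = 40, max_side = 15) {
  x <- sample.int(canvas - 2, 1)
  y <- sample.int(canvas - 2, 1)
  tibble::tibble(
    xmin = x, ymin = y,
    xmax = x + sample.int(max_side, 1),
    ymax = y + sample.int(max_side, 1)
  )
}

# Exhaustive maximum one-to-one matching oracle: the largest number of
# prediction/truth pairs with IOU strictly above the threshold.
optimal_match_oracle <- function(pred, truth, iou_threshold = 0.5) {
  np <- nrow(pred); nt <- nrow(truth)
  if (np == 0 || nt == 0) return(0L)
  edge <- matrix(FALSE, np, nt)
  for (i in seq_len(np)) {
    edge[i, ] <- stemscan::iou(pred[i, ], truth) > iou_threshold
  }
  best <- 0L
  recurse <- function(i, used) {
    if (i > np) return(0L)
    top <- recurse(i + 1L, used) # skip prediction i
    for (j in which(edge[i, ] & !used)) {
      used[j] <- TRUE
      top <- max(top, 1L + recurse(i + 1L, used))
      used[j] <- FALSE
    }
    top
  }
  recurse(1L, logical(nt))
}
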