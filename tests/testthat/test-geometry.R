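test_that("iou handles identity, disjoint and partial overlap", {
  a <- c(0, 0, 10, 10)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, c(20, 20, 30, 30)), 0)
  expect_equal(iou(a, c(5, 0, 15, 10)), 50 / 150)
  expect_equal(iou(a, c(5, 0, 15, 10)), iou(c(5, 0, 15, 10), a))
})

test_that("overlap_fraction uses the smaller area as denominator", {
  big <- c(0, 0, 20, 20)
  small <- c(5, 5, 10, 10)
  expect_equal(overlap_fraction(big, small), 1)
  expect_equal(overlap_fraction(small, big), 1)
  expect_equal(overlap_fraction(big, c(30, 30, 40, 40)), 0)
  expect_equal(overlap_fraction(c(0, 0, 10, 10), c(5, 0, 15, 10)), 0.5)
})

test_that("degenerate boxes are rejected", {
  expect_error(iou(c(0, 0, 0, 10), c(0, 0, 5, 5)), "Degenerate")
  expect_error(overlap_fraction(c(0, 0, 5, 5), c(3, 3, 3, 8)), "Degenerate")
  expect_error(box_area(c(2, 2, 1, 3)), "Degenerate")
})

test_that("iou and overlap_fraction agree with the integer-pixel oracle", {
  set.seed(101)
  for (k in 1:200) {
    a <- random_int_box()
    b <- random_int_box()
    oracle <- pixel_overlap_oracle(a, b)
    expect_equal(iou(a, b), oracle$iou, tolerance = 1e-9)
    expect_equal(overlap_fraction(a, b), oracle$overlap_fraction, tolerance = 1e-9)
    # union >= min area, so iou can never exceed the overlap fraction
    expect_lte(iou(a, b), overlap_fraction(a, b) + 1e-12)
  }
})

test_that("plan_tiling enumerates anchors by the stride rule", {
  p1 <- plan_tiling(1000, 1000)
  expect_equal(nrow(p1), 1)
  expect_equal(c(p1$x, p1$y), c(0, 0))

  p2 <- plan_tiling(1500, 1000)
  expect_equal(sort(unique(p2$x)), c(0, 500))
  expect_equal(nrow(p2), 2)

  expect_equal(nrow(plan_tiling(6000, 4000)), 77)
  expect_error(plan_tiling(800, 600, overlap = 1), "overlap")
  expect_error(plan_tiling(800, 600, overlap = -0.1), "overlap")
})

test_that("small images give one clipped patch and tilings cover every pixel", {
  p <- plan_tiling(300, 200)
  expect_equal(nrow(p), 1)
  expect_equal(c(p$width, p$height), c(300, 200))

  set.seed(7)
  for (k in 1:10) {
    w <- sample(50:900, 1)
    h <- sample(50:900, 1)
    plan <- plan_tiling(w, h, patch_size = 256, overlap = 0.5)
    covered <- matrix(FALSE, h, w)
    for (i in seq_len(nrow(plan))) {
      covered[plan$y[i] + seq_len(plan$height[i]),
              plan$x[i] + seq_len(plan$width[i])] <- TRUE
    }
    expect_true(all(covered))
  }
})

test_that("merge_across_patches removes duplicates, keeps the higher score", {
  two <- tibble::tibble(xmin = c(0, 0), ymin = c(0, 0), xmax = c(10, 10),
                        ymax = c(10, 10), score = c(0.9, 0.85))
  m <- merge_across_patches(two)
  expect_equal(nrow(m), 1)
  expect_equal(m$score, 0.9)

  apart <- tibble::tibble(xmin = c(0, 5), ymin = c(0, 0), xmax = c(10, 15),
                          ymax = c(10, 10), score = c(0.9, 0.85))
  expect_equal(nrow(merge_across_patches(apart)), 2) # overlap fraction 0.5

  expect_equal(nrow(merge_across_patches(two[0, ])), 0)
})

test_that("greedy suppression resolves chains in score order", {
  # A overlaps B, B overlaps C, A and C disjoint: keep A (best) and C
  chain <- tibble::tibble(
    xmin = c(0, 8, 16), ymin = 0, xmax = c(10, 18, 26), ymax = 10,
    score = c(0.9, 0.8, 0.7)
  )
  expect_equal(overlap_fraction(chain[1, ], chain[2, ]), 0.2)
  m <- merge_across_patches(chain, overlap_threshold = 0.2)
  expect_equal(sort(m$xmin), c(0, 16))
})

test_that("merge_across_patches is idempotent on random detection sets", {
  set.seed(55)
  for (k in 1:20) {
    dets <- dplyr::bind_rows(lapply(1:15, function(i) random_int_box()))
    dets$score <- round(runif(15), 2)
    once <- merge_across_patches(dets)
    twice <- merge_across_patches(once)
    expect_equal(once, twice)
    # no surviving pair may reach the overlap threshold
    if (nrow(once) > 1) {
      for (i in seq_len(nrow(once) - 1)) {
        expect_true(all(overlap_fraction(once[i, ], once[-seq_len(i), ]) < 0.75))
      }
    }
  }
})

test_that("filter_by_score keeps the boundary and preserves order", {
  dets <- tibble::tibble(xmin = 0:2, ymin = 0, xmax = 10:12, ymax = 10,
                         score = c(0.95, 0.80, 0.79))
  kept <- filter_by_score(dets)
  expect_equal(kept$score, c(0.95, 0.80))
  expect_equal(nrow(filter_by_score(dets[0, ])), 0)
  expect_equal(nrow(filter_by_score(dets, threshold = 0.99)), 0)
})
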