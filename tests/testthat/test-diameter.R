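test_that("gray conversion applies the fixed luma weights without rounding", {
  expect_equal(to_gray(0, 0, 0), 0)
  expect_equal(to_gray(255, 255, 255), 254.9745)
  expect_equal(to_gray(100, 0, 0), 29.89)
  expect_error(to_gray(-1, 0, 0), "0, 255")
  expect_error(to_gray(0, 256, 0), "0, 255")
  # linearity in the channel vector
  set.seed(3)
  c0 <- runif(3, 0, 255)
  for (alpha in c(0.2, 0.5, 0.9)) {
    expect_equal(to_gray(alpha * c0[1], alpha * c0[2], alpha * c0[3]),
                 alpha * to_gray(c0[1], c0[2], c0[3]))
  }
})

test_that("profiles are constant on uniform patches and clipped to the box", {
  gray <- matrix(120, 60, 60)
  box <- c(10, 10, 40, 40)
  profs <- extract_profiles(gray, box)
  expect_setequal(unique(profs$direction), c(0, 45, 90, 135))
  expect_true(all(abs(profs$value - 120) < 1e-9))
  diag_len <- sqrt(2) * 30
  for (th in c(0, 45, 90, 135)) {
    p <- profs[profs$direction == th, ]
    expect_lte(max(p$position) - min(p$position), diag_len + 1e-9)
    expect_true(any(p$position == 0)) # passes through the center
  }
  expect_error(extract_profiles(gray, c(0, 0, 3, 3)), "4x4")
})

test_that("profiles across a centered annulus are bimodal and symmetric", {
  img <- make_annulus(10)
  sz <- nrow(img)
  profs <- extract_profiles(img, c(sz / 2 - 14, sz / 2 - 14, sz / 2 + 14, sz / 2 + 14))
  for (th in c(0, 45, 90, 135)) {
    p <- profs[profs$direction == th, ]
    left_max <- p$position[p$position < 0][which.max(p$value[p$position < 0])]
    right_max <- p$position[p$position > 0][which.max(p$value[p$position > 0])]
    expect_equal(abs(left_max), 10, tolerance = 0.1)
    expect_equal(right_max, 10, tolerance = 0.1)
  }
})

test_that("diameter_from_profile returns peak separation or an invalid state", {
  pos <- seq(-15, 15, by = 0.5)
  val <- rep(10, length(pos))
  val[pos == -10] <- 200
  val[pos == 10] <- 200
  expect_equal(diameter_from_profile(pos, val), 20)

  ramp <- seq_along(pos) # monotone: maximum at an endpoint
  expect_true(is.na(diameter_from_profile(pos, ramp)))

  flat <- rep(5, length(pos)) # no unique maximum on either side
  expect_true(is.na(diameter_from_profile(pos, flat)))

  expect_error(diameter_from_profile(seq(-1, 1, 0.5), rep(1, 5)), "5 samples")
})

test_that("diameter is invariant under affine gray rescaling", {
  img <- make_annulus(8)
  sz <- nrow(img)
  det <- tibble::tibble(xmin = sz / 2 - 11, ymin = sz / 2 - 11,
                        xmax = sz / 2 + 11, ymax = sz / 2 + 11, score = 1)
  d1 <- measure_stem(img, det, 1)$mean_px
  d2 <- measure_stem(0.4 * img + 30, det, 1)$mean_px
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("rendered annuli are measured to within a pixel of the ring diameter", {
  img <- make_annulus(8) # ring-center diameter 16 px, blur sigma 1
  sz <- nrow(img)
  det <- tibble::tibble(xmin = sz / 2 - 11, ymin = sz / 2 - 11,
                        xmax = sz / 2 + 11, ymax = sz / 2 + 11, score = 1)
  m <- measure_stem(img, det, resolution = 0.12)
  expect_true(m$valid)
  expect_equal(m$n_valid, 4)
  expect_equal(m$mean_px, 16, tolerance = 1)
  expect_equal(m$diameter_mm, m$mean_px * 0.12)
  # circular stem: the four directions agree within two sampling steps
  expect_lt(max(c(m$d0, m$d45, m$d90, m$d135)) -
              min(c(m$d0, m$d45, m$d90, m$d135)), 1)
})

test_that("an elliptical stem averages between its axes", {
  sz <- 61
  ax <- seq_len(sz) - 0.5
  cx <- sz / 2
  # ellipse with semi-axes 10 (x) and 8 (y): ring where the scaled radius is 1
  rr <- sqrt(outer(((ax - cx) / 8)^2, ((ax - cx) / 10)^2, "+"))
  img <- stemscan:::gaussian_blur(60 + 120 * exp(-(rr - 1)^2 / (2 * 0.015)), 1)
  det <- tibble::tibble(xmin = cx - 13, ymin = cx - 13,
                        xmax = cx + 13, ymax = cx + 13, score = 1)
  m <- measure_stem(img, det, 1)
  expect_equal(m$d0, 20, tolerance = 1)   # along the long axis
  expect_equal(m$d90, 16, tolerance = 1)  # along the short axis
  expect_gt(m$mean_px, 16)
  expect_lt(m$mean_px, 20)
})

test_that("a stem with fewer than two usable directions is invalid", {
  # two bright dots on the horizontal axis only: the 0-degree profile has two
  # proper borders, every other direction is flat
  sz <- 41L
  img <- matrix(10, sz, sz)
  c0 <- ceiling(sz / 2) # pixel whose center sits at the box center
  img[c0, c0 - 10] <- 200
  img[c0, c0 + 10] <- 200
  det <- tibble::tibble(xmin = c0 - 0.5 - 14, ymin = c0 - 0.5 - 14,
                        xmax = c0 - 0.5 + 14, ymax = c0 - 0.5 + 14, score = 1)
  m <- measure_stem(img, det, 1)
  expect_equal(m$d0, 20, tolerance = 0.5)
  expect_equal(m$n_valid, 1)
  expect_false(m$valid)
})
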