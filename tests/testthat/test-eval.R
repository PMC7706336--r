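test_that("matching counts TP, FP and FN one-to-one", {
  truth <- tibble::tibble(xmin = c(0, 30, 60), ymin = 0,
                          xmax = c(20, 50, 80), ymax = 20)
  pred <- dplyr::mutate(truth, score = c(0.9, 0.95, 0.85))
  expect_equal(as.list(match_detections(pred, truth)),
               list(tp = 3L, fp = 0L, fn = 0L))

  # one detection overlapping two truths can only claim one of them
  twins <- tibble::tibble(xmin = c(0, 2), ymin = 0, xmax = c(20, 22), ymax = 20)
  one <- tibble::tibble(xmin = 1, ymin = 0, xmax = 21, ymax = 20, score = 0.9)
  cnt <- match_detections(one, twins)
  expect_equal(as.list(cnt), list(tp = 1L, fp = 0L, fn = 1L))

  expect_equal(match_detections(pred[0, ], truth)$fn, 3L)
  expect_equal(match_detections(pred, truth[0, ])$fp, 3L)
})

test_that("matching at the IOU threshold is strict", {
  a <- tibble::tibble(xmin = 0, ymin = 0, xmax = 10, ymax = 10, score = 1)
  # shifted so that IOU is exactly 1/3 < 0.5, and an identical pair with IOU 1
  half <- tibble::tibble(xmin = 5, ymin = 0, xmax = 15, ymax = 10)
  expect_equal(match_detections(a, half)$tp, 0L)
  expect_equal(match_detections(a, a[, 1:4], iou_threshold = 0.999)$tp, 1L)
  expect_equal(match_detections(a, a[, 1:4], iou_threshold = 1)$tp, 0L)
})

test_that("greedy matching never beats and usually equals the optimal assignment", {
  set.seed(202)
  equal_count <- 0
  trials <- 120
  for (k in seq_len(trials)) {
    nt <- sample(2:8, 1)
    np <- sample(2:8, 1)
    truth <- dplyr::bind_rows(lapply(seq_len(nt), function(i) random_int_box(30, 10)))
    pred <- dplyr::bind_rows(lapply(seq_len(np), function(i) {
      b <- truth[sample.int(nt, 1), ]
      jit <- sample(-3:3, 4, replace = TRUE)
      tibble::tibble(xmin = b$xmin + jit[1], ymin = b$ymin + jit[2],
                     xmax = b$xmax + jit[3], ymax = b$ymax + jit[4])
    }))
    ok <- pred$xmax > pred$xmin & pred$ymax > pred$ymin
    pred <- pred[ok, ]
    if (nrow(pred) == 0) next
    pred$score <- round(runif(nrow(pred)), 2)
    greedy_tp <- match_detections(pred, truth)$tp
    optimal_tp <- optimal_match_oracle(pred, truth)
    expect_lte(greedy_tp, optimal_tp)
    if (greedy_tp == optimal_tp) equal_count <- equal_count + 1
  }
  expect_gt(equal_count / trials, 0.9)
})

test_that("precision, recall and bias follow their definitions", {
  m <- detection_metrics(tibble::tibble(tp = 9L, fp = 1L, fn = 0L))
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 1.0)
  expect_error(detection_metrics(tibble::tibble(tp = 0L, fp = 0L, fn = 2L)), "tp \\+ fp")
  expect_error(detection_metrics(tibble::tibble(tp = 0L, fp = 2L, fn = 0L)), "tp \\+ fn")
})

test_that("bias reproduces published-style precision/recall pairs", {
  expect_equal(round(detection_bias(0.95, 0.97), 2), -0.02)
  expect_equal(round(detection_bias(0.94, 0.95), 2), -0.01)
  expect_equal(round(detection_bias(0.96, 0.95), 2), 0.01)
  expect_equal(detection_bias(0.95, 0.95), 0)
  # sign convention: negative exactly when recall exceeds precision
  set.seed(4)
  p <- runif(50, 0.5, 1)
  r <- runif(50, 0.5, 1)
  expect_equal(detection_bias(p, r) < 0, r > p)
  # the alternative text-form convention flips the sign
  expect_equal(round(detection_bias(0.95, 0.97, convention = "inverse"), 2), 0.02)
})

test_that("regression metrics and RRMSE follow the reference-mean convention", {
  x <- c(100, 200, 300, 400)
  m <- regression_metrics(x, x)
  expect_equal(m$slope, 1)
  expect_equal(m$intercept, 0)
  expect_equal(m$r2, 1)
  expect_equal(m$rmse, 0)

  expect_equal(round(relative_rmse(24.45, 352), 2), 6.95)
  expect_equal(round(relative_rmse(40.25, 662), 2), 6.08)
  expect_error(regression_metrics(1:4, 1:5), "Lengths")
})

test_that("summary statistics include the n-1 coefficient of variation", {
  # two-point vectors with a prescribed mean m and sd s: m +/- s/sqrt(2)
  v1 <- 493 + c(-1, 1) * 132 / sqrt(2)
  s1 <- summarize_values(v1)
  expect_equal(s1$mean, 493)
  expect_equal(s1$sd, 132)
  expect_equal(round(s1$cv, 2), 26.77)

  v2 <- 561 + c(-1, 1) * 179 / sqrt(2)
  expect_equal(round(summarize_values(v2)$cv, 2), 31.91)

  s0 <- summarize_values(c(5, 5, 5))
  expect_equal(c(s0$sd, s0$cv, s0$range), c(0, 0, 0))
  expect_error(summarize_values(7), "at least 2")
})

test_that("leave-one-out regression is exact on noiseless linear data", {
  df <- tibble::tibble(x = 1:12, y = 3 + 2 * (1:12))
  f <- loocv_regression(df, "y", "x")
  expect_equal(f$metrics$r2, 1)
  expect_equal(f$metrics$rmse, 0, tolerance = 1e-10)
  expect_s3_class(autoplot(f), "ggplot")
  expect_equal(nrow(tidy(f)), 12)
  expect_equal(glance(f)$model, "x")
})

test_that("leave-one-out R2 collapses when the response is independent", {
  set.seed(37)
  df <- tibble::tibble(x = rnorm(37), y = rnorm(37, 100, 5))
  f <- loocv_regression(df, "y", "x")
  expect_lt(f$metrics$r2, 0.15)
  # out-of-fold predictions stay near the training mean
  expect_lt(max(abs(f$predictions$predicted - 100)), 5)
})

test_that("rank-deficient predictor tables are rejected", {
  df <- tibble::tibble(x = 1:10, z = 2 * (1:10), y = rnorm(10))
  expect_error(loocv_regression(df, "y", c("x", "z")), "Rank-deficient")
})

test_that("heritability spans its extremes and is affine equivariant", {
  g <- rep(letters[1:4], each = 5)
  between_only <- rep(c(1, 5, 9, 13), each = 5)
  expect_equal(heritability(g, between_only)$h2, 1)

  set.seed(13)
  noise_only <- rnorm(20)
  h0 <- heritability(g, noise_only)
  expect_lt(h0$h2, 0.5)
  expect_gte(h0$vg, 0)

  set.seed(14)
  mixed <- rnorm(20) + rep(rnorm(4, 0, 2), each = 5)
  h1 <- heritability(g, mixed)
  expect_equal(heritability(g, mixed + 100)$h2, h1$h2)
  expect_equal(heritability(g, 3 * mixed)$h2, h1$h2, tolerance = 1e-12)

  expect_error(heritability(rep("a", 6), rnorm(6)), "2 genotypes")
})

test_that("heritability uses the harmonic mean under unbalanced replication", {
  set.seed(15)
  reps <- c(2, 4, 8)
  g <- rep(c("a", "b", "c"), times = reps)
  y <- rnorm(sum(reps)) + rep(c(0, 3, 6), times = reps)
  h <- heritability(g, y)
  expect_equal(h$harmonic_reps, 3 / sum(1 / reps))
  ms <- anova(aov(y ~ factor(g)))$`Mean Sq`
  expect_equal(h$vg, max((ms[1] - ms[2]) / (3 / sum(1 / reps)), 0))
  expect_equal(glance(h)$h2, h$h2)
})
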