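# Independent reference implementations used as oracles in this file.

# Direct O(n * m) Gaussian convolution with symmetric reflection padding.
direct_gaussian <- function(y, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  m <- length(y)
  # edge-repeating (half-sample symmetric) reflection: 0 -> 1, m+1 -> m
  reflect <- function(i) {
    while (i < 1L || i > m) {
      if (i < 1L) i <- 1L - i
      if (i > m) i <- 2L * m + 1L - i
    }
    i
  }
  vapply(seq_len(m), function(i) {
    sum(vapply(-r:r, function(d) k[d + r + 1L] * y[reflect(i + d)],
               numeric(1)))
  }, numeric(1))
}

# Brute-force strict local maxima with plateau midpoints.
brute_peaks <- function(y, threshold) {
  m <- length(y)
  out <- integer()
  i <- 2L
  while (i <= m - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < m && y[j + 1L] == y[i]) j <- j + 1L
      if (j < m && y[j + 1L] < y[i]) {
        if (y[i] >= threshold) out <- c(out, i + (j - i) %/% 2L)
        i <- j + 1L
        next
      }
      i <- j + 1L
      next
    }
    i <- i + 1L
  }
  out
}

test_that("the Gaussian kernel has unit sum and constants pass through", {
  for (s in c(0.7, 1, 2, 3.5)) {
    k <- lumbartrack:::gaussian_kernel(s)
    expect_equal(sum(k), 1, tolerance = 1e-15)
    expect_equal(k, rev(k))
  }
  const <- smooth_curve(rep(2.5, 40), sigma = 2)
  expect_equal(const$y, rep(2.5, 40), tolerance = 1e-12)
})

test_that("smooth_curve equals direct convolution to 1e-12", {
  set.seed(314)
  for (i in 1:25) {
    m <- sample(10:120, 1)
    sigma <- stats::runif(1, 0.5, 4)
    y <- stats::rnorm(m)
    expect_lt(max(abs(smooth_curve(y, sigma)$y - direct_gaussian(y, sigma))),
              1e-12)
  }
  expect_error(smooth_curve(c(1, 2), sigma = 2),
               class = "lumbartrack_validation_error")
  expect_error(smooth_curve(1:10, sigma = 0),
               class = "lumbartrack_validation_error")
})

test_that("detect_peaks matches a brute-force scan", {
  set.seed(2718)
  for (i in 1:40) {
    y <- smooth_curve(stats::rnorm(sample(20:100, 1)), sigma = 1)$y
    got <- detect_peaks(y, threshold = 0.1)
    expect_equal(got$index, brute_peaks(y, 0.1), info = paste("curve", i))
  }
})

test_that("plateau peaks resolve to their midpoint", {
  y <- c(0, 1, 1, 1, 0, 0.2, 0.9, 0.2)
  p <- detect_peaks(y, threshold = 0.3)
  expect_equal(p$index, c(3L, 7L))
  expect_equal(p$height, c(1, 0.9))
})

test_that("peaks below the retention threshold are discarded", {
  y <- c(0, 0.25, 0, 0.5, 0)
  expect_equal(detect_peaks(y, threshold = 0.3)$index, 4L)
  expect_equal(nrow(detect_peaks(y * 0.5, threshold = 0.3)), 0L)
  # a curve whose maximum is 0.25 never yields a retained peak at 0.3
  set.seed(5)
  for (i in 1:10) {
    y <- smooth_curve(abs(stats::rnorm(50)), sigma = 1)$y
    y <- y / max(y) * 0.25
    expect_equal(nrow(detect_peaks(y, threshold = 0.3)), 0L)
    expect_gt(nrow(detect_peaks(y, threshold = 0.2)), 0L)
  }
})

make_curve <- function(label, x, peak_at, height = 1) {
  y <- height * exp(-(x - peak_at)^2 / 8)
  structure(list(segment_label = label, x = x, y = y, smoothing_sigma = 2,
                 valid = TRUE), class = "contribution_curve")
}

test_that("classification matches peaks in canonical order", {
  x <- seq(0, 20, by = 0.5)
  curves <- structure(list(L1L2 = make_curve("L1L2", x, 18),
                           L2L3 = make_curve("L2L3", x, 14),
                           L3L4 = make_curve("L3L4", x, 10)),
                      class = "contribution_curves", phase = "extension2")
  cls <- classify_sequence(curves)
  expect_s3_class(cls, "sequence_classification")
  expect_true(cls$matches_canonical)
  expect_false(cls$excluded)
  expect_equal(cls$ordered_peaks$segment_label, c("L3L4", "L2L3", "L1L2"))

  # reversed order fails
  rev_curves <- structure(list(L1L2 = make_curve("L1L2", x, 10),
                               L2L3 = make_curve("L2L3", x, 14),
                               L3L4 = make_curve("L3L4", x, 18)),
                          class = "contribution_curves", phase = "extension2")
  expect_false(classify_sequence(rev_curves)$matches_canonical)

  # a missing (sub-threshold) peak fails
  weak <- curves
  weak$L2L3 <- make_curve("L2L3", x, 14, height = 0.25)
  expect_false(classify_sequence(weak)$matches_canonical)

  # position ties break toward non-match
  tied <- curves
  tied$L2L3 <- make_curve("L2L3", x, 10)
  expect_false(classify_sequence(tied)$matches_canonical)
})

test_that("the last-phase window restricts which peaks count", {
  x <- seq(0, 20, by = 0.5)
  curves <- structure(list(L1L2 = make_curve("L1L2", x, 18),
                           L2L3 = make_curve("L2L3", x, 14),
                           L3L4 = make_curve("L3L4", x, 2)),
                      class = "contribution_curves", phase = "extension2")
  # over the whole phase the order is canonical
  expect_true(classify_sequence(curves, last_phase_fraction = 1)$matches_canonical)
  # a last-third window (x >= 13.33) excludes the early L3L4 peak
  cls <- classify_sequence(curves, last_phase_fraction = 1 / 3)
  expect_false(cls$matches_canonical)
  expect_equal(cls$window, c(20 - 20 / 3, 20), tolerance = 1e-12)
  expect_error(classify_sequence(curves, last_phase_fraction = 0),
               class = "lumbartrack_validation_error")
})

test_that("an invalid curve excludes the recording from classification", {
  x <- seq(0, 20, by = 0.5)
  curves <- structure(list(L1L2 = make_curve("L1L2", x, 18),
                           L2L3 = make_curve("L2L3", x, 14),
                           L3L4 = make_curve("L3L4", x, 10)),
                      class = "contribution_curves", phase = "extension2")
  curves$L2L3$valid <- FALSE
  cls <- classify_sequence(curves)
  expect_true(cls$excluded)
  expect_true(is.na(cls$matches_canonical))
})

test_that("contribution_curves restricts, orients and smooths by phase", {
  rec <- generate_kinematics(segment_kinematics_spec(), motion_protocol(),
                             seed = 8)
  series <- segment_series_from_poses(as_poses(rec))
  cum <- compute_cumulative(series)
  ph <- split_phases(cum)
  cum_block <- compute_cumulative(series, c("L1L2", "L2L3", "L3L4"))
  ext2 <- contribution_curves(series, cum_block, ph, phase = "extension2")
  expect_equal(names(ext2), c("L1L2", "L2L3", "L3L4"))
  expect_equal(attr(ext2, "phase"), "extension2")
  expect_equal(length(ext2$L1L2$y), length(ph$extension2))
  expect_equal(ext2$L1L2$x, cum_block$values_deg[ph$extension2])
  # flexion curves are sign-flipped and measured as flexion progress
  flex <- contribution_curves(series, cum_block, ph, phase = "flexion")
  expect_equal(flex$L1L2$x,
               cum_block$values_deg[ph$flexion[1] - 1L] -
                 cum_block$values_deg[ph$flexion])
  expect_equal(flex$L1L2$y,
               smooth_curve(-series$L1L2$increments_deg[ph$flexion], 2)$y)
})

test_that("consistency_summary reproduces the example cohort bookkeeping", {
  cls <- example_cohort_classifications()
  s <- consistency_summary(cls)
  expect_equal(s$per_time_point$n_analyzable, c(10L, 11L))
  expect_equal(s$per_time_point$n_canonical, c(8L, 7L))
  expect_equal(s$per_time_point$fraction_pct, c(80, 700 / 11))
  expect_equal(s$overall$n, 21L)
  expect_equal(s$overall$n_canonical, 15L)
  expect_equal(s$n_excluded, 1L)
  # P5, P7 fail at both time points; P9, P11 at T2; P1 is excluded at T1
  expect_equal(sort(s$consistent_participants),
               sort(paste0("P", c(2, 3, 4, 6, 8, 10))))
  # T2 is below the 80% rule, so the cohort is not consistent
  expect_false(s$cohort_consistent)
  expect_error(consistency_summary(data.frame(participant = "a")),
               class = "lumbartrack_validation_error")
})
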