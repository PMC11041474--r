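make_poses <- function(label, rot, valid = TRUE) {
  data.frame(frame_index = seq_along(rot), vertebra_label = label,
             rotation_deg = rot, tx_px = 0, ty_px = 0, match_score = 1,
             valid = valid, stringsAsFactors = FALSE)
}

test_that("segment increments are exact differences of relative rotation", {
  up <- make_poses("L3", c(0, 1, 3, 6))
  lo <- make_poses("L4", c(0, 0.5, 1, 1.5))
  s <- compute_segment_series(up, lo)
  expect_s3_class(s, "segment_series")
  expect_equal(s$segment_label, "L3L4")
  # relative angles 0, 0.5, 2, 4.5 -> increments 0.5, 1.5, 2.5
  expect_equal(s$increments_deg, c(0.5, 1.5, 2.5))
  expect_equal(s$valid_mask, rep(TRUE, 3))
  flipped <- compute_segment_series(up, lo, extension_sign = -1)
  expect_equal(flipped$increments_deg, -c(0.5, 1.5, 2.5))
})

test_that("frame pairs touching an invalid pose are masked", {
  up <- make_poses("L3", c(0, 1, 3, 6), valid = c(TRUE, FALSE, TRUE, TRUE))
  lo <- make_poses("L4", c(0, 0, 0, 0))
  s <- compute_segment_series(up, lo)
  expect_equal(s$valid_mask, c(FALSE, FALSE, TRUE))
})

test_that("segment series validation catches mismatched tables", {
  up <- make_poses("L3", c(0, 1, 2))
  lo <- make_poses("L4", c(0, 1))
  expect_error(compute_segment_series(up, lo),
               class = "lumbartrack_validation_error")
  expect_error(compute_segment_series(up, make_poses("L4", c(0, 1, 2)),
                                      extension_sign = 2),
               class = "lumbartrack_validation_error")
  expect_error(compute_segment_series(data.frame(a = 1), lo),
               class = "lumbartrack_validation_error")
})

test_that("segment_series_from_poses builds every adjacent pair", {
  rec <- generate_kinematics(segment_kinematics_spec(), motion_protocol(),
                             seed = 1)
  series <- segment_series_from_poses(as_poses(rec, noisy = FALSE))
  expect_equal(names(series), c("L1L2", "L2L3", "L3L4", "L4L5", "L5S1"))
  expect_error(segment_series_from_poses(as_poses(rec), c("L1", "T12")),
               class = "lumbartrack_validation_error")
})

test_that("cumulative block rotation is the running sum of block increments", {
  up <- make_poses("L1", c(0, 1, 2, 3))
  mid <- make_poses("L2", c(0, 0.5, 1, 1.5))
  lo <- make_poses("L3", rep(0, 4))
  series <- list(compute_segment_series(up, mid),
                 compute_segment_series(mid, lo))
  cum <- compute_cumulative(series)
  # L1L2 increments 0.5 each, L2L3 increments 0.5 each -> block 1 per pair
  expect_equal(cum$values_deg, c(1, 2, 3))
  expect_equal(cum$block_labels, c("L1L2", "L2L3"))
  one <- compute_cumulative(series, "L2L3")
  expect_equal(one$values_deg, c(0.5, 1, 1.5))
  expect_error(compute_cumulative(series, "L4L5"),
               class = "lumbartrack_validation_error")
})

test_that("split_phases finds triangle-wave turning points exactly", {
  # extension to +10 over 30 pairs, flexion to -10 over 40, extension back
  v <- c(seq(1 / 3, 10, length.out = 30),
         seq(10, -10, length.out = 41)[-1],
         seq(-10, 10, length.out = 31)[-1])
  cum <- structure(list(block_labels = "all", values_deg = v,
                        valid_mask = rep(TRUE, length(v))),
                   class = "cumulative_axis")
  ph <- split_phases(cum)
  expect_equal(ph$boundaries, c(30L, 70L))
  expect_equal(ph$extension1, 1:30)
  expect_equal(ph$flexion, 31:70)
  expect_equal(ph$extension2, 71:100)
})

test_that("split_phases matches the generator's phase labels", {
  rec <- generate_kinematics(segment_kinematics_spec(), motion_protocol(),
                             seed = 11)
  series <- segment_series_from_poses(as_poses(rec, noisy = FALSE))
  ph <- split_phases(compute_cumulative(series))
  # frame pair i spans frames i, i+1; compare against true phase of frame i+1
  true_phase <- as.character(rec$phase[-1])
  # boundaries must fall within 2 frame pairs of the true transitions
  expect_lt(abs(ph$boundaries[1] - max(which(true_phase == "extension1"))), 3)
  expect_lt(abs(ph$boundaries[2] - max(which(true_phase == "flexion"))), 3)
})

test_that("split_phases rejects monotone recordings", {
  cum <- structure(list(block_labels = "all", values_deg = 1:50,
                        valid_mask = rep(TRUE, 50)),
                   class = "cumulative_axis")
  expect_error(split_phases(cum), class = "lumbartrack_validation_error")
  expect_error(split_phases(1:50), class = "lumbartrack_validation_error")
})
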