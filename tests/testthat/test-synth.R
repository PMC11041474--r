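test_that("motion_protocol validates its inputs", {
  expect_error(motion_protocol(duration_s = -1), class = "lumbartrack_validation_error")
  expect_error(motion_protocol(phase_plan = c(a = 0.5, b = 0.6)),
               class = "lumbartrack_validation_error")
  expect_error(motion_protocol(start_u = 1), class = "lumbartrack_validation_error")
  expect_error(motion_protocol(n_frames = 1), class = "lumbartrack_validation_error")
})

test_that("protocol trajectory runs start_u -> 1 -> 0 -> 1 with labeled phases", {
  proto <- motion_protocol(n_frames = 101L, start_u = 0.5)
  traj <- lumbartrack:::protocol_trajectory(proto)
  expect_equal(traj$u[1], 0.5)
  expect_equal(traj$u[101], 1)
  # end of extension1 at 20% of the cycle, end of flexion at 60%
  expect_equal(traj$u[21], 1)
  expect_equal(traj$u[61], 0)
  expect_true(all(traj$u >= 0 & traj$u <= 1))
  expect_equal(levels(traj$phase), c("extension1", "flexion", "extension2"))
  expect_equal(as.character(traj$phase[c(2, 40, 90)]),
               c("extension1", "flexion", "extension2"))
  # boundary frames belong to the earlier phase
  expect_equal(as.character(traj$phase[21]), "extension1")
  expect_equal(as.character(traj$phase[61]), "flexion")
})

test_that("minimum-jerk profile has smooth endpoints", {
  mj <- lumbartrack:::minimum_jerk
  expect_equal(mj(0), 0)
  expect_equal(mj(1), 1)
  # zero velocity at both ends
  h <- 1e-6
  expect_lt(abs(mj(h) - mj(0)) / h, 1e-4)
  expect_lt(abs(mj(1) - mj(1 - h)) / h, 1e-4)
  tau <- seq(0, 1, length.out = 200)
  expect_true(all(diff(mj(tau)) >= 0))
})

test_that("bump_cdf conserves the range and is monotone", {
  for (ctr in c(0.25, 0.5, 0.9)) {
    expect_equal(lumbartrack:::bump_cdf(0, ctr, 0.1), 0)
    expect_equal(lumbartrack:::bump_cdf(1, ctr, 0.1), 1)
    u <- seq(0, 1, length.out = 100)
    expect_true(all(diff(lumbartrack:::bump_cdf(u, ctr, 0.1)) > 0))
  }
})

test_that("generate_kinematics stacks angles over a fixed sacrum", {
  rec <- generate_kinematics(segment_kinematics_spec(), motion_protocol(),
                             seed = 7)
  expect_s3_class(rec, "ground_truth_recording")
  expect_equal(dim(rec$angles), c(104L, 6L))
  expect_equal(colnames(rec$angles), c("L1", "L2", "L3", "L4", "L5", "S1"))
  expect_equal(unname(rec$angles[, "S1"]), rep(0, 104))
  # relative angle of adjacent vertebrae reproduces segment kinematics
  spec <- rec$spec
  for (s in seq_along(spec$segment_labels)) {
    rel <- rec$angles[, s] - rec$angles[, s + 1L]
    expect_equal(rel, spec$total_range_deg[s] *
                   lumbartrack:::bump_cdf(rec$u, spec$contribution_center[s],
                                          spec$contribution_width[s]),
                 tolerance = 1e-12)
  }
  expect_equal(rec$peak_sequence_true,
               c("L5S1", "L4L5", "L3L4", "L2L3", "L1L2"))
})

test_that("the per-phase segment excursion equals the specified range share", {
  rec <- generate_kinematics(segment_kinematics_spec(), motion_protocol(),
                             seed = 1)
  # over flexion (u: 1 -> 0) every segment sweeps its full range
  flex <- rec$phase == "flexion"
  i0 <- min(which(flex)) - 1L   # last extension1 frame, u = 1
  i1 <- max(which(flex))        # u = 0
  rel <- rec$angles[, -6L] - rec$angles[, -1L]
  # frames need not land exactly on the phase boundaries (104 frames over
  # a 0.2/0.4/0.4 plan), so the sampled excursion is marginally short
  expect_equal(unname(rel[i0, ] - rel[i1, ]), rec$spec$total_range_deg,
               tolerance = 1e-3)
})

test_that("the recording is deterministic given the seed, and noise only
           affects reported increments", {
  a <- generate_kinematics(segment_kinematics_spec(), motion_protocol(), seed = 5)
  b <- generate_kinematics(segment_kinematics_spec(), motion_protocol(), seed = 5)
  c <- generate_kinematics(segment_kinematics_spec(), motion_protocol(), seed = 6)
  expect_identical(a$segment_increments_reported, b$segment_increments_reported)
  expect_identical(a$angles, c$angles)
  expect_identical(a$segment_increments_true, c$segment_increments_true)
  expect_false(identical(a$segment_increments_reported,
                         c$segment_increments_reported))
})

test_that("generate_kinematics does not disturb the global RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_kinematics(segment_kinematics_spec(), motion_protocol(),
                                seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("as_poses reconstructs true angles and reported increments", {
  rec <- generate_kinematics(segment_kinematics_spec(), motion_protocol(),
                             seed = 2)
  clean <- as_poses(rec, noisy = FALSE)
  expect_equal(clean$rotation_deg, as.vector(rec$angles))
  noisy <- as_poses(rec, noisy = TRUE)
  series <- segment_series_from_poses(noisy)
  for (s in seq_along(rec$spec$segment_labels)) {
    expect_equal(series[[rec$spec$segment_labels[s]]]$increments_deg,
                 unname(rec$segment_increments_reported[, s]),
                 tolerance = 1e-9)
  }
})

test_that("rendering is deterministic and produces templates at the median frame", {
  st <- small_stack()
  st2 <- render_frames(small_recording(), small_geometry(), seed = 4)
  expect_identical(st$frames, st2$frames)
  expect_equal(length(st$frames), 21L)
  expect_equal(st$reference_frame_index, 11L)
  expect_equal(names(st$templates), c("L2", "L3", "L4"))
  for (tp in st$templates) {
    expect_s3_class(tp, "template_area")
    expect_equal(tp$reference_frame_index, 11L)
    expect_true(all(tp$polygon[, 1] >= 0 & tp$polygon[, 1] < 230))
    expect_true(all(tp$polygon[, 2] >= 0 & tp$polygon[, 2] < 300))
  }
  expect_true(all(vapply(st$frames, function(f)
    all(f >= 0 & f <= 1), logical(1))))
  expect_equal(nrow(st$out_of_view), 0L)
})

test_that("a drifting column is reported out of view with a warning", {
  expect_warning(
    render_frames(small_recording(),
                  small_geometry(drift_px_per_frame = c(12, 0)), seed = 4),
    "field of view")
  st <- drifted_stack()
  expect_gt(nrow(st$out_of_view), 0L)
  expect_true(all(c("frame_index", "vertebra_label") %in%
                    names(st$out_of_view)))
})

test_that("the occlusion band reduces contrast only inside the band", {
  plain <- small_stack()
  occl <- render_frames(small_recording(),
                        small_geometry(occlusion_band = c(150, 230)),
                        seed = 4)
  f0 <- plain$frames[[11]]
  f1 <- occl$frames[[11]]
  expect_equal(f0[1:140, ], f1[1:140, ])
  expect_lt(stats::sd(f1[160:220, ]), stats::sd(f0[160:220, ]))
})
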