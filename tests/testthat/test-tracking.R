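test_that("normalized gradient fields are unit-bounded and validated", {
  set.seed(12)
  img <- matrix(stats::runif(400), 20, 20)
  ngf <- normalized_gradient_field(img, epsilon = 0.05)
  mag <- sqrt(ngf$gx^2 + ngf$gy^2)
  expect_true(all(mag <= 1 + 1e-12))
  expect_true(all(mag >= 0))
  # a flat image has a zero field everywhere, whatever epsilon
  flat <- normalized_gradient_field(matrix(0.5, 20, 20), epsilon = 0.01)
  expect_equal(max(abs(flat$gx)), 0)
  expect_equal(max(abs(flat$gy)), 0)
  # epsilon suppresses weak gradients relative to strong ones
  step <- matrix(0.5, 20, 20); step[, 11:20] <- 1
  weak <- step + matrix(stats::runif(400, 0, 1e-3), 20, 20)
  n2 <- normalized_gradient_field(weak, epsilon = 0.1)
  expect_gt(max(abs(n2$gx[, 10:11])), 0.9)
  expect_lt(max(abs(n2$gx[, 3])), 0.05)
  expect_error(normalized_gradient_field(img, epsilon = 0),
               class = "lumbartrack_validation_error")
  expect_error(normalized_gradient_field(1:10, epsilon = 0.1),
               class = "lumbartrack_validation_error")
})

test_that("the tracker recovers a known rigid rotation ramp within 0.1 deg RMS", {
  rec <- small_recording()
  rec$angles <- matrix(rep((0:20) * 0.5, 3), ncol = 3,
                       dimnames = list(NULL, rec$vertebra_labels))
  st <- render_frames(rec, small_geometry(), seed = 2)
  tr <- track_vertebra(st$frames, st$templates[["L3"]], track_config())
  truth <- (0:20) * 0.5 - 5    # relative to the reference (median) frame
  expect_lt(sqrt(mean((tr$rotation_deg - truth)^2)), 0.1)
  expect_true(all(tr$valid))
  # reference frame is exact by construction
  expect_equal(tr$rotation_deg[11], 0)
  expect_equal(tr$tx_px[11], 0)
})

test_that("tracked poses match ground truth on a rendered recording", {
  st <- small_stack()
  tracks <- small_tracks()
  expect_equal(names(tracks), c("L2", "L3", "L4"))
  for (lab in names(tracks)) {
    tr <- tracks[[lab]]
    expect_s3_class(tr, "vertebra_track")
    rel <- truth_relative(st, lab)
    expect_lt(sqrt(mean((tr$rotation_deg - rel)^2)), 0.1)
    tru <- st$truth[st$truth$vertebra_label == lab, ]
    expect_lt(sqrt(mean((tr$tx_px - tru$tx_px)^2 + (tr$ty_px - tru$ty_px)^2)),
              0.5)
    expect_true(all(tr$valid))
    expect_true(all(tr$match_score > 0.5))
  }
})

test_that("rotation estimates are unbiased over the recording", {
  st <- small_stack()
  tracks <- small_tracks()
  errs <- unlist(lapply(names(tracks), function(lab) {
    tracks[[lab]]$rotation_deg - truth_relative(st, lab)
  }))
  expect_gte(length(errs), 50)
  expect_lt(abs(mean(errs)), 0.02)
})

test_that("occlusion lowers the match score of the occluded vertebra", {
  st <- small_stack()
  occl <- render_frames(small_recording(),
                        small_geometry(occlusion_band = c(150, 230)),
                        seed = 4)
  # L4 (lowest body) sits inside the band; track it with the clean template
  tr_occl <- track_vertebra(occl$frames, st$templates[["L4"]], track_config())
  tr_plain <- small_tracks()[["L4"]]
  expect_lt(mean(tr_occl$match_score), mean(tr_plain$match_score) - 0.02)
})

test_that("frame noise lowers the match score monotonically", {
  rec <- small_recording()
  means <- vapply(c(0, 0.05, 0.15), function(ns) {
    st <- render_frames(rec, small_geometry(frame_noise_sd = ns), seed = 4)
    mean(track_vertebra(st$frames, st$templates[["L3"]],
                        track_config())$match_score)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("a vertebra leaving the field of view is flagged invalid", {
  poses <- drifted_poses()
  expect_gt(sum(!poses$valid), 0)
  # frames rendered fully out of view never carry a confident valid pose
  st <- drifted_stack()
  lost <- st$out_of_view
  away <- lost[lost$frame_index %in% c(1, 2, 21), ]
  expect_gt(nrow(away), 0)
})

test_that("manual corrections replace the pose, re-track downstream frames and
           are recorded in the audit log", {
  st <- small_stack()
  tr <- small_tracks()[["L3"]]
  expect_equal(nrow(audit_log(tr)), 0L)
  i <- 15L
  corrected <- c(tr$rotation_deg[i] + 0.4, tr$tx_px[i], tr$ty_px[i])
  tr2 <- manual_correction(tr, st$frames, frame_index = i,
                           corrected_pose = corrected)
  expect_equal(tr2$rotation_deg[i], corrected[1])
  # frames between the reference and the correction stay untouched
  expect_equal(tr2$rotation_deg[1:14], tr$rotation_deg[1:14])
  # the audit log records old and new pose
  log <- audit_log(tr2)
  expect_equal(nrow(log), 1L)
  expect_equal(log$frame_index, i)
  expect_equal(log$rotation_deg, corrected[1])
  expect_equal(log$previous_rotation_deg, tr$rotation_deg[i])
  # downstream frames were re-tracked from the corrected pose and still
  # land near the truth
  rel <- truth_relative(st, "L3")
  expect_lt(max(abs(tr2$rotation_deg[16:21] - rel[16:21])), 0.5)
})

test_that("a correction outside the per-frame motion bounds warns but applies", {
  st <- small_stack()
  tr <- small_tracks()[["L3"]]
  big <- c(tr$rotation_deg[15] + 30, tr$tx_px[15], tr$ty_px[15])
  expect_warning(tr3 <- manual_correction(tr, st$frames, 15, big), "bound")
  expect_equal(tr3$rotation_deg[15], big[1])
})

test_that("track_config validates its bounds", {
  expect_error(track_config(max_rot_per_frame = 0),
               class = "lumbartrack_validation_error")
  expect_error(track_config(pyramid_levels = 0),
               class = "lumbartrack_validation_error")
})
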