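# Shared fixtures. Rendering and tracking are the expensive stages, so the
# small phantom stack and its tracks are built once per test run and reused
# (helpers persist across test files within one test_dir() call).

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env, inherits = FALSE)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env, inherits = FALSE)
}

# A two-segment (L2-L4), noise-free kinematics spec small enough to render
# and track quickly while exercising realistic rotation magnitudes.
small_spec <- function() {
  segment_kinematics_spec(
    segment_labels = c("L2L3", "L3L4"),
    total_range_deg = c(4, 5),
    contribution_center = c(0.6, 0.4),
    contribution_width = c(0.15, 0.15),
    noise_sd_deg = 0
  )
}

small_protocol <- function(n_frames = 21L) {
  motion_protocol(n_frames = n_frames,
                  phase_plan = c(extension1 = 0.2, flexion = 0.4,
                                 extension2 = 0.4))
}

small_geometry <- function(...) {
  phantom_geometry(image_size = c(230, 300), body_width_px = 80,
                   body_height_px = 50, spacing_px = 80, ...)
}

small_recording <- function() {
  fixture("small_recording", function() {
    generate_kinematics(small_spec(), small_protocol(), seed = 3)
  })
}

small_stack <- function() {
  fixture("small_stack", function() {
    render_frames(small_recording(), small_geometry(), seed = 4)
  })
}

small_tracks <- function() {
  fixture("small_tracks", function() {
    st <- small_stack()
    attr(track_all(st$frames, st$templates), "tracks")
  })
}

# Drifted variant whose column leaves the field of view partway through.
drifted_stack <- function() {
  fixture("drifted_stack", function() {
    suppressWarnings(render_frames(
      small_recording(),
      small_geometry(drift_px_per_frame = c(12, 0)), seed = 4))
  })
}

drifted_poses <- function() {
  fixture("drifted_poses", function() {
    st <- drifted_stack()
    track_all(st$frames, st$templates)
  })
}

# Ground-truth rotation of one vertebra relative to the reference frame.
truth_relative <- function(stack, label) {
  tru <- stack$truth[stack$truth$vertebra_label == label, ]
  tru <- tru[order(tru$frame_index), ]
  tru$angle_deg - tru$angle_deg[stack$reference_frame_index]
}

# Config matching the small two-segment spec, for analyze_recording/run_full.
# The pattern block and canonical order are restricted to the two simulated
# segments (L3L4 peaks before L2L3 given the contribution centers).
small_config <- function(...) {
  pipeline_config(kinematics = small_spec(), protocol = small_protocol(),
                  geometry = small_geometry(),
                  pattern_block = c("L2L3", "L3L4"),
                  canonical_pattern = c("L3L4", "L2L3"), ...)
}
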