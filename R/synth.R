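#' Acquisition protocol for a simulated extension-flexion-extension cycle
#'
#' Describes the cine acquisition the simulator emulates: a seated subject
#' moves from maximum extension through maximum flexion and back to maximum
#' extension while sagittal frames are pulsed at a fixed rate. Defaults match
#' a 14 s cycle recorded at 7.5 frames per second yielding 104 frames.
#'
#' @param duration_s Cycle duration in seconds.
#' @param frame_rate_hz Pulse rate in frames per second.
#' @param n_frames Number of acquired frames (at least 2). The default of 104
#'   is kept as stated for the emulated protocol even though
#'   `duration_s * frame_rate_hz` rounds to 105; override if exact products
#'   are wanted.
#' @param phase_plan Named numeric vector of phase fractions of the cycle, in
#'   order `extension1`, `flexion`, `extension2`; must sum to 1. Defaults are
#'   proportional to each phase's excursion along the cumulative-motion
#'   coordinate given `start_u`.
#' @param start_u Starting position on the cumulative-motion coordinate
#'   (0 = maximum flexion, 1 = maximum extension). The default 0.5 emulates a
#'   neutral seated start, so the cycle is neutral, maximum extension,
#'   maximum flexion, maximum extension.
#' @return An object of class `motion_protocol`.
#' @export
#' @examples
#' motion_protocol()
motion_protocol <- function(duration_s = 14,
                            frame_rate_hz = 7.5,
                            n_frames = 104L,
                            phase_plan = c(extension1 = 0.2,
                                           flexion = 0.4,
                                           extension2 = 0.4),
                            start_u = 0.5) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop_validation("duration_s must be a positive number", "duration_s")
  }
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0) {
    stop_validation("frame_rate_hz must be a positive number", "frame_rate_hz")
  }
  if (!is.numeric(n_frames) || length(n_frames) != 1L || n_frames < 2) {
    stop_validation("n_frames must be a single integer >= 2", "n_frames")
  }
  if (length(phase_plan) < 2L || any(phase_plan <= 0)) {
    stop_validation("phase_plan needs at least two positive fractions", "phase_plan")
  }
  if (abs(sum(phase_plan) - 1) > 1e-8) {
    stop_validation("phase_plan fractions must sum to 1", "phase_plan")
  }
  if (is.null(names(phase_plan)) || any(!nzchar(names(phase_plan)))) {
    names(phase_plan) <- c("extension1", "flexion", "extension2")[seq_along(phase_plan)]
  }
  if (!is.numeric(start_u) || length(start_u) != 1L || start_u < 0 || start_u >= 1) {
    stop_validation("start_u must lie in [0, 1)", "start_u")
  }
  structure(
    list(duration_s = duration_s, frame_rate_hz = frame_rate_hz,
         n_frames = as.integer(n_frames), phase_plan = phase_plan,
         start_u = start_u),
    class = "motion_protocol"
  )
}

#' @export
print.motion_protocol <- function(x, ...) {
  cat(sprintf("Motion protocol: %g s at %g fps, %d frames\n",
              x$duration_s, x$frame_rate_hz, x$n_frames))
  cat("Phases:", paste(sprintf("%s (%.0f%%)", names(x$phase_plan),
                               100 * x$phase_plan), collapse = ", "), "\n")
  invisible(x)
}

#' Per-segment kinematics specification for the simulator
#'
#' Each lumbar segment contributes a unimodal, Gaussian-shaped share of the
#' overall motion, placed along the normalized cumulative-motion coordinate
#' `u` in `[0, 1]` (`u = 0` maximum flexion, `u = 1` maximum extension). The
#' ordering of `contribution_center` values is the ground-truth peak
#' sequence. Default amplitudes place roughly half the sagittal range in the
#' lower two segments, with the upper three segments peaking late in
#' extension in the canonical order L3L4, L2L3, L1L2.
#'
#' @param segment_labels Ordered segment labels, cranial to caudal.
#' @param total_range_deg Positive per-segment full-cycle rotation range in
#'   degrees (recycled if scalar).
#' @param contribution_center Per-segment bump center as a fraction of
#'   cumulative motion, in `[0, 1]`.
#' @param contribution_width Per-segment bump width (fraction, > 0).
#' @param noise_sd_deg Standard deviation in degrees of the additive
#'   zero-mean Gaussian measurement noise applied to *reported* inter-frame
#'   increments (scalar or per segment). The default 0.15 puts the 0.3
#'   degree peak-retention threshold at about two standard deviations.
#' @return An object of class `segment_kinematics_spec`.
#' @export
segment_kinematics_spec <- function(segment_labels = c("L1L2", "L2L3", "L3L4",
                                                       "L4L5", "L5S1"),
                                    total_range_deg = c(8, 9, 11, 12, 8),
                                    contribution_center = c(0.90, 0.80, 0.70,
                                                            0.45, 0.25),
                                    contribution_width = c(0.10, 0.10, 0.10,
                                                           0.15, 0.15),
                                    noise_sd_deg = 0.15) {
  ns <- length(segment_labels)
  if (ns < 1L) stop_validation("at least one segment is required", "segment_labels")
  if (anyDuplicated(segment_labels)) {
    stop_validation("segment_labels must be unique", "segment_labels")
  }
  rec <- function(x, nm) {
    if (length(x) == 1L) x <- rep(x, ns)
    if (length(x) != ns) {
      stop_validation(sprintf("%s must have length 1 or %d", nm, ns), nm)
    }
    x
  }
  total_range_deg <- rec(total_range_deg, "total_range_deg")
  contribution_center <- rec(contribution_center, "contribution_center")
  contribution_width <- rec(contribution_width, "contribution_width")
  noise_sd_deg <- rec(noise_sd_deg, "noise_sd_deg")
  if (any(!is.finite(total_range_deg)) || any(total_range_deg <= 0)) {
    stop_validation("total_range_deg must be positive for every segment",
                    "total_range_deg")
  }
  if (any(contribution_center < 0) || any(contribution_center > 1)) {
    stop_validation("contribution_center must lie in [0, 1]", "contribution_center")
  }
  if (any(!is.finite(contribution_width)) || any(contribution_width <= 0)) {
    stop_validation("contribution_width must be positive", "contribution_width")
  }
  if (any(noise_sd_deg < 0)) {
    stop_validation("noise_sd_deg must be non-negative", "noise_sd_deg")
  }
  structure(
    list(segment_labels = as.character(segment_labels),
         total_range_deg = total_range_deg,
         contribution_center = contribution_center,
         contribution_width = contribution_width,
         noise_sd_deg = noise_sd_deg),
    class = "segment_kinematics_spec"
  )
}

# Minimum-jerk position profile on [0, 1]: smooth start/stop so increment
# series have no spikes at phase boundaries.
minimum_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# Cumulative-motion coordinate per frame plus per-frame phase labels.
# Boundary frames belong to the earlier phase. Odd phases ascend to maximum
# extension (u = 1), even phases descend to maximum flexion (u = 0); the
# first phase starts from the neutral start_u, so u runs
# start_u -> 1 -> 0 -> 1 for the default three-phase cycle.
protocol_trajectory <- function(protocol) {
  n <- protocol$n_frames
  s <- if (n == 1L) 0 else (seq_len(n) - 1) / (n - 1)
  bounds <- cumsum(protocol$phase_plan)
  lower <- c(0, bounds[-length(bounds)])
  phase_idx <- pmin(findInterval(s, c(0, bounds), left.open = TRUE,
                                 rightmost.closed = TRUE) + 0L,
                    length(bounds))
  phase_idx[s == 0] <- 1L
  tau <- (s - lower[phase_idx]) / (bounds[phase_idx] - lower[phase_idx])
  from <- ifelse(phase_idx == 1L, protocol$start_u %||% 0,
                 ifelse(phase_idx %% 2L == 1L, 0, 1))
  to <- ifelse(phase_idx %% 2L == 1L, 1, 0)
  u <- unname(from + (to - from) * minimum_jerk(tau))
  list(u = u,
       phase = factor(names(protocol$phase_plan)[phase_idx],
                      levels = names(protocol$phase_plan)))
}

# CDF of the Gaussian contribution bump truncated to u in [0, 1]; maps 0 -> 0
# and 1 -> 1 exactly so ranges are conserved per phase.
bump_cdf <- function(u, center, width) {
  lo <- stats::pnorm((0 - center) / width)
  hi <- stats::pnorm((1 - center) / width)
  (stats::pnorm((u - center) / width) - lo) / (hi - lo)
}

#' Generate a ground-truth lumbar recording
#'
#' Produces per-frame absolute sagittal angles for L1 to S1 and the
#' noise-free and reported (noise-added) per-segment inter-frame rotation
#' increments implied by a segment kinematics specification and a motion
#' protocol. The sacrum is held fixed (emulating pelvic fixation); each
#' vertebra's angle is the sum of the segment angles below it, so the
#' relative rotation of adjacent vertebrae reproduces the specified segment
#' kinematics exactly.
#'
#' @param spec A [segment_kinematics_spec()].
#' @param protocol A [motion_protocol()].
#' @param seed Integer seed; the recording is deterministic given the seed.
#' @return An object of class `ground_truth_recording` with elements
#'   `angles` (frames x vertebrae matrix, degrees, extension positive),
#'   `u` (cumulative-motion coordinate per frame), `phase` (per frame),
#'   `segment_increments_true` and `segment_increments_reported`
#'   ((frames - 1) x segments matrices) and `peak_sequence_true`.
#' @export
#' @examples
#' rec <- generate_kinematics(segment_kinematics_spec(), motion_protocol(), seed = 1)
#' dim(rec$angles)
#' rec$peak_sequence_true
generate_kinematics <- function(spec, protocol = motion_protocol(), seed = 1L) {
  if (!inherits(spec, "segment_kinematics_spec")) {
    stop_validation("spec must be a segment_kinematics_spec", "spec")
  }
  if (!inherits(protocol, "motion_protocol")) {
    stop_validation("protocol must be a motion_protocol", "protocol")
  }
  traj <- protocol_trajectory(protocol)
  n <- protocol$n_frames
  ns <- length(spec$segment_labels)

  # Per-segment relative angle (upper minus lower vertebra), extension +.
  seg_angle <- vapply(seq_len(ns), function(s) {
    spec$total_range_deg[s] *
      bump_cdf(traj$u, spec$contribution_center[s], spec$contribution_width[s])
  }, numeric(n))
  colnames(seg_angle) <- spec$segment_labels

  inc_true <- diff(seg_angle)
  inc_reported <- with_seed(seed, {
    inc_true + vapply(seq_len(ns), function(s) {
      stats::rnorm(n - 1L, 0, spec$noise_sd_deg[s])
    }, numeric(n - 1L))
  })
  colnames(inc_reported) <- spec$segment_labels

  # Vertebra labels from segment labels: "L1L2" -> upper "L1", lower "L2".
  uppers <- substr(spec$segment_labels, 1L, 2L)
  lowers <- substr(spec$segment_labels, 3L, 4L)
  vertebrae <- c(uppers, lowers[ns])
  angles <- matrix(0, n, ns + 1L, dimnames = list(NULL, vertebrae))
  for (v in rev(seq_len(ns))) {
    angles[, v] <- angles[, v + 1L] + seg_angle[, v]
  }

  structure(
    list(protocol = protocol, spec = spec, seed = as.integer(seed),
         vertebra_labels = vertebrae,
         angles = angles, u = traj$u, phase = traj$phase,
         segment_increments_true = inc_true,
         segment_increments_reported = inc_reported,
         peak_sequence_true = spec$segment_labels[order(spec$contribution_center)]),
    class = "ground_truth_recording"
  )
}

#' @export
print.ground_truth_recording <- function(x, ...) {
  cat(sprintf("Ground-truth recording: %d frames, %d vertebrae (%s)\n",
              nrow(x$angles), ncol(x$angles),
              paste(x$vertebra_labels, collapse = ", ")))
  cat("True peak sequence:", paste(x$peak_sequence_true, collapse = " -> "), "\n")
  invisible(x)
}

#' Convert a ground-truth recording to a pose table
#'
#' Builds the per-frame, per-vertebra pose table the tracking stage would
#' emit, so the analysis stages can be run without imaging. With
#' `noisy = TRUE`, vertebra angles are reconstructed from the reported
#' (noise-added) segment increments so downstream segment series reproduce
#' the simulated measurement noise; translations are zero.
#'
#' @param recording A [generate_kinematics()] result.
#' @param noisy Use reported (noisy) increments rather than the noise-free truth.
#' @return A data frame with columns `frame_index`, `vertebra_label`,
#'   `rotation_deg`, `tx_px`, `ty_px`, `match_score`, `valid`.
#' @export
as_poses <- function(recording, noisy = TRUE) {
  if (!inherits(recording, "ground_truth_recording")) {
    stop_validation("recording must be a ground_truth_recording", "recording")
  }
  n <- nrow(recording$angles)
  ns <- ncol(recording$segment_increments_true)
  if (noisy) {
    seg0 <- recording$angles[1L, -ncol(recording$angles)] -
      recording$angles[1L, -1L]
    seg <- rbind(seg0, sweep(apply(recording$segment_increments_reported, 2L,
                                   cumsum), 2L, seg0, FUN = "+"))
    angles <- matrix(0, n, ns + 1L)
    for (v in rev(seq_len(ns))) angles[, v] <- angles[, v + 1L] + seg[, v]
  } else {
    angles <- recording$angles
  }
  data.frame(
    frame_index = rep(seq_len(n), times = ns + 1L),
    vertebra_label = rep(recording$vertebra_labels, each = n),
    rotation_deg = as.vector(angles),
    tx_px = 0, ty_px = 0, match_score = 1, valid = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Phantom geometry for rendered sagittal frame stacks
#'
#' Controls how the simulator draws vertebral bodies: each vertebra is a
#' high-contrast, internally textured trapezoid rotating about its centroid
#' at the ground-truth angle. An optional horizontal occlusion band washes
#' out contrast over the caudal vertebrae, mimicking pelvic overprojection;
#' an optional global drift translates the column across frames.
#'
#' @param image_size `c(width, height)` in pixels; default 1024 x 1024.
#' @param body_width_px,body_height_px Vertebral body size in pixels.
#' @param spacing_px Centroid-to-centroid vertical spacing.
#' @param center_x,top_y Column placement (defaults center the stack).
#' @param taper Fractional narrowing of the cranial edge of each body.
#' @param texture_cell_px Cell size of the random internal texture grid.
#' @param texture_amp Texture amplitude around the body base intensity.
#' @param base_intensity,background Body and background grey levels in `[0, 1]`.
#' @param background_amp Amplitude of the static smooth background field.
#' @param frame_noise_sd Per-frame additive pixel noise sd (0 disables; with
#'   0, a motionless recording renders pixel-identical frames).
#' @param occlusion_band `NULL` or `c(y0, y1)` rows (0-based) of a
#'   low-contrast band.
#' @param occlusion_strength Blend factor towards flat grey inside the band.
#' @param drift_px_per_frame `c(dx, dy)` global translation per frame.
#' @return An object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(image_size = c(1024L, 1024L),
                             body_width_px = 120, body_height_px = 70,
                             spacing_px = 105,
                             center_x = NULL, top_y = NULL,
                             taper = 0.12,
                             texture_cell_px = 8, texture_amp = 0.22,
                             base_intensity = 0.65, background = 0.12,
                             background_amp = 0.04,
                             frame_noise_sd = 0,
                             occlusion_band = NULL,
                             occlusion_strength = 0.85,
                             drift_px_per_frame = c(0, 0)) {
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  if (any(image_size < 16)) {
    stop_validation("image_size must be at least 16 px", "image_size")
  }
  if (body_width_px <= 0 || body_height_px <= 0 || spacing_px <= 0) {
    stop_validation("body size and spacing must be positive", "body_width_px")
  }
  if (!is.null(occlusion_band) && length(occlusion_band) != 2L) {
    stop_validation("occlusion_band must be NULL or c(y0, y1)", "occlusion_band")
  }
  structure(
    list(image_size = as.integer(image_size),
         body_width_px = body_width_px, body_height_px = body_height_px,
         spacing_px = spacing_px, center_x = center_x, top_y = top_y,
         taper = taper, texture_cell_px = texture_cell_px,
         texture_amp = texture_amp, base_intensity = base_intensity,
         background = background, background_amp = background_amp,
         frame_noise_sd = frame_noise_sd,
         occlusion_band = occlusion_band,
         occlusion_strength = occlusion_strength,
         drift_px_per_frame = drift_px_per_frame),
    class = "phantom_geometry"
  )
}

# Local-frame trapezoid corners (4 x 2), centered on the centroid.
body_corners_local <- function(geom) {
  hw <- geom$body_width_px / 2
  hh <- geom$body_height_px / 2
  k <- 1 - geom$taper
  rbind(c(-hw * k, -hh), c(hw * k, -hh), c(hw, hh), c(-hw, hh))
}

#' Render a ground-truth recording as a sagittal frame stack
#'
#' Draws one grayscale frame per time point with each vertebra at its
#' ground-truth pose, and returns the median-frame polygon outlines as
#' tracker templates. Rendering is deterministic given `seed`. A vertebra
#' whose polygon leaves the field of view is flagged (and a warning is
#' issued), mirroring recordings that must be excluded when a vertebra
#' cannot be followed.
#'
#' @param recording A [generate_kinematics()] result.
#' @param geometry A [phantom_geometry()].
#' @param seed Integer seed for texture and optional pixel noise.
#' @return An object of class `phantom_stack`: list with `frames` (list of
#'   height x width matrices in `[0, 1]`), `templates` (list of
#'   [template_area()]), `truth` (data frame: frame, vertebra, angle_deg,
#'   tx_px, ty_px), `out_of_view` (data frame), `reference_frame_index`.
#' @export
render_frames <- function(recording, geometry = phantom_geometry(), seed = 1L) {
  if (!inherits(recording, "ground_truth_recording")) {
    stop_validation("recording must be a ground_truth_recording", "recording")
  }
  if (!inherits(geometry, "phantom_geometry")) {
    stop_validation("geometry must be a phantom_geometry", "geometry")
  }
  n <- nrow(recording$angles)
  nv <- ncol(recording$angles)
  w <- geometry$image_size[1]; h <- geometry$image_size[2]
  cx <- geometry$center_x %||% (w / 2)
  ty0 <- geometry$top_y %||% ((h - (nv - 1) * geometry$spacing_px) / 2)
  centroids <- cbind(rep(cx, nv), ty0 + (seq_len(nv) - 1) * geometry$spacing_px)
  local <- body_corners_local(geometry)
  ref_idx <- (n + 1L) %/% 2L
  drift <- geometry$drift_px_per_frame

  with_seed(seed, {
    # Static smooth background field.
    cell_bg <- 32
    gx <- ceiling(w / cell_bg) + 2L; gy <- ceiling(h / cell_bg) + 2L
    bg_grid <- matrix(stats::runif(gx * gy), gy, gx)
    px <- rep(seq_len(w) - 1, each = h); py <- rep(seq_len(h) - 1, times = w)
    background <- matrix(
      geometry$background + geometry$background_amp *
        (bilinear_sample(bg_grid, px / cell_bg, py / cell_bg) - 0.5) * 2,
      h, w)

    # Per-vertebra internal texture grids in local coordinates.
    margin <- 4
    hw <- geometry$body_width_px / 2 + margin
    hh <- geometry$body_height_px / 2 + margin
    tcell <- geometry$texture_cell_px
    tx_n <- ceiling(2 * hw / tcell) + 2L
    ty_n <- ceiling(2 * hh / tcell) + 2L
    textures <- lapply(seq_len(nv), function(v) {
      matrix(stats::runif(tx_n * ty_n), ty_n, tx_n)
    })

    frames <- vector("list", n)
    oov <- list()
    templates <- vector("list", nv)

    for (f in seq_len(n)) {
      canvas <- background
      if (geometry$frame_noise_sd > 0) {
        canvas <- canvas + matrix(stats::rnorm(h * w, 0, geometry$frame_noise_sd), h, w)
      }
      dshift <- (f - ref_idx) * drift
      for (v in seq_len(nv)) {
        theta <- recording$angles[f, v]
        ctr <- centroids[v, ] + dshift
        corners <- sweep(local %*% t(rot2(theta)), 2L, ctr, FUN = "+")
        if (any(corners[, 1] < 0) || any(corners[, 1] > w - 1) ||
            any(corners[, 2] < 0) || any(corners[, 2] > h - 1)) {
          oov[[length(oov) + 1L]] <- data.frame(
            frame_index = f, vertebra_label = recording$vertebra_labels[v],
            stringsAsFactors = FALSE)
        }
        if (f == ref_idx) {
          templates[[v]] <- template_area(recording$vertebra_labels[v],
                                          corners, ref_idx)
        }
        # Rasterize within the clamped bounding box by inverse mapping.
        x0 <- max(0L, floor(min(corners[, 1])) - 1L)
        x1 <- min(w - 1L, ceiling(max(corners[, 1])) + 1L)
        y0 <- max(0L, floor(min(corners[, 2])) - 1L)
        y1 <- min(h - 1L, ceiling(max(corners[, 2])) + 1L)
        if (x1 < x0 || y1 < y0) next
        bx <- seq.int(x0, x1); by <- seq.int(y0, y1)
        gxp <- rep(bx, each = length(by)); gyp <- rep(by, times = length(bx))
        lp <- sweep(cbind(gxp, gyp), 2L, ctr) %*% rot2(theta)   # rows %*% t(R(-theta))
        lx <- lp[, 1]; ly <- lp[, 2]
        # Signed distance to the trapezoid as min over edge half-planes
        # (inward-positive); 1 px soft edge.
        nrm <- function(a, b) {          # inward normal distance to edge a->b
          ex <- b[1] - a[1]; ey <- b[2] - a[2]
          len <- sqrt(ex^2 + ey^2)
          ((lx - a[1]) * ey - (ly - a[2]) * ex) / len
        }
        d <- pmin(nrm(local[2, ], local[1, ]), nrm(local[3, ], local[2, ]),
                  nrm(local[4, ], local[3, ]), nrm(local[1, ], local[4, ]))
        alpha <- pmin(pmax(d + 0.5, 0), 1)
        sel <- alpha > 0
        if (!any(sel)) next
        tex <- bilinear_sample(textures[[v]],
                               (lx[sel] + hw) / tcell, (ly[sel] + hh) / tcell)
        val <- geometry$base_intensity +
          geometry$texture_amp * (tex - 0.5) * 2
        idx <- cbind(gyp[sel] + 1L, gxp[sel] + 1L)
        canvas[idx] <- canvas[idx] * (1 - alpha[sel]) + val * alpha[sel]
      }
      if (!is.null(geometry$occlusion_band)) {
        rows <- seq.int(max(0, geometry$occlusion_band[1]),
                        min(h - 1, geometry$occlusion_band[2])) + 1L
        s <- geometry$occlusion_strength
        canvas[rows, ] <- canvas[rows, ] * (1 - s) + s * 0.5
      }
      frames[[f]] <- pmin(pmax(canvas, 0), 1)
    }

    oov <- if (length(oov)) do.call(rbind, oov) else
      data.frame(frame_index = integer(), vertebra_label = character(),
                 stringsAsFactors = FALSE)
    if (nrow(oov)) {
      warning(sprintf(
        "vertebra outside the field of view in %d frame(s): %s",
        nrow(oov), paste(unique(oov$vertebra_label), collapse = ", ")),
        call. = FALSE)
    }
    truth <- data.frame(
      frame_index = rep(seq_len(n), times = nv),
      vertebra_label = rep(recording$vertebra_labels, each = n),
      angle_deg = as.vector(recording$angles),
      tx_px = rep((seq_len(n) - ref_idx) * drift[1], times = nv),
      ty_px = rep((seq_len(n) - ref_idx) * drift[2], times = nv),
      stringsAsFactors = FALSE)

    names(templates) <- recording$vertebra_labels
    structure(
      list(frames = frames, templates = templates, truth = truth,
           geometry = geometry, out_of_view = oov,
           reference_frame_index = ref_idx,
           vertebra_labels = recording$vertebra_labels),
      class = "phantom_stack")
  })
}

#' @export
print.phantom_stack <- function(x, ...) {
  cat(sprintf("Phantom stack: %d frames of %d x %d px, %d vertebrae\n",
              length(x$frames), ncol(x$frames[[1]]), nrow(x$frames[[1]]),
              length(x$templates)))
  if (nrow(x$out_of_view)) {
    cat(sprintf("  %d frame/vertebra pairs out of the field of view\n",
                nrow(x$out_of_view)))
  }
  invisible(x)
}
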