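#' Normalized gradient field of an image
#'
#' Computes the per-pixel image gradient (central differences in the
#' interior, one-sided at the borders) normalized by
#' `sqrt(|grad I|^2 + epsilon^2)`. The resulting vectors have magnitude at
#' most 1: close to 0 in flat regions, close to 1 where the gradient
#' magnitude greatly exceeds `epsilon`. Matching normalized gradient fields
#' makes rigid registration robust to global intensity changes.
#'
#' @param image 2-D numeric matrix (grayscale frame).
#' @param epsilon Positive regularization; gradients of magnitude around
#'   `epsilon` and below are treated as noise.
#' @return List with matrices `gx`, `gy` (unit-bounded components) and `mag`
#'   (raw gradient magnitude).
#' @export
#' @examples
#' f <- matrix(rep(c(0, 0, 1, 1), each = 4), 4, 4)
#' ngf <- normalized_gradient_field(f, epsilon = 1e-3)
#' range(sqrt(ngf$gx^2 + ngf$gy^2))
normalized_gradient_field <- function(image, epsilon) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop_validation("image must be a 2-D numeric matrix", "image")
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop_validation("epsilon must be a single positive number", "epsilon")
  }
  g <- raw_gradients(image)
  den <- sqrt(g$mag^2 + epsilon^2)
  list(gx = g$gx / den, gy = g$gy / den, mag = g$mag)
}

# Central-difference gradients (one-sided at the borders), unnormalized.
raw_gradients <- function(image) {
  h <- nrow(image); w <- ncol(image)
  if (h < 2L || w < 2L) stop_validation("image must be at least 2 x 2", "image")
  gx <- matrix(0, h, w)
  gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (image[, 3:w] - image[, 1:(w - 2)]) / 2
  gx[, 1] <- image[, 2] - image[, 1]
  gx[, w] <- image[, w] - image[, w - 1]
  gy[2:(h - 1), ] <- (image[3:h, ] - image[1:(h - 2), ]) / 2
  gy[1, ] <- image[2, ] - image[1, ]
  gy[h, ] <- image[h, ] - image[h - 1, ]
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Tracker search configuration
#'
#' Bounds and numerical settings of the frame-to-frame rigid 2-D search.
#'
#' @param max_rot_per_frame Rotation search bound per frame, degrees.
#' @param max_trans_per_frame Translation search bound per frame, pixels.
#' @param pyramid_levels Coarse-to-fine levels (x2 downsampling each).
#' @param epsilon Normalized-gradient-field regularization; `NULL` selects
#'   10 percent of the median gradient magnitude over the template region.
#' @param min_score Match-score floor below which a pose is flagged invalid.
#' @param refine Run continuous Nelder-Mead refinement after the grid search.
#' @return An object of class `track_config`.
#' @export
track_config <- function(max_rot_per_frame = 6,
                         max_trans_per_frame = 20,
                         pyramid_levels = 3L,
                         epsilon = NULL,
                         min_score = 0.05,
                         refine = TRUE) {
  if (max_rot_per_frame <= 0 || max_trans_per_frame <= 0) {
    stop_validation("search bounds must be positive", "max_rot_per_frame")
  }
  if (pyramid_levels < 1L) {
    stop_validation("pyramid_levels must be >= 1", "pyramid_levels")
  }
  structure(
    list(max_rot_per_frame = max_rot_per_frame,
         max_trans_per_frame = max_trans_per_frame,
         pyramid_levels = as.integer(pyramid_levels),
         epsilon = epsilon, min_score = min_score, refine = isTRUE(refine)),
    class = "track_config"
  )
}

as_frame_list <- function(frames) {
  if (inherits(frames, "phantom_stack")) return(frames$frames)
  if (is.list(frames)) return(frames)
  if (is.array(frames) && length(dim(frames)) == 3L) {
    return(lapply(seq_len(dim(frames)[1]), function(i) frames[i, , ]))
  }
  stop_validation("frames must be a list of matrices or an n x h x w array",
                  "frames")
}

# Reference data per pyramid level: template pixel coordinates, their
# reference NGF vectors, polygon centroid and epsilon (all in level units).
prepare_reference <- function(ref_image, template, config) {
  levels <- list()
  img <- ref_image
  poly0 <- template$polygon
  for (l in seq_len(config$pyramid_levels) - 1L) {
    s <- 2^l
    poly <- poly0 / s
    x0 <- max(0L, floor(min(poly[, 1]))); x1 <- min(ncol(img) - 1L, ceiling(max(poly[, 1])))
    y0 <- max(0L, floor(min(poly[, 2]))); y1 <- min(nrow(img) - 1L, ceiling(max(poly[, 2])))
    if (x1 <= x0 || y1 <= y0) break
    gx <- rep(seq.int(x0, x1), each = y1 - y0 + 1L)
    gy <- rep(seq.int(y0, y1), times = x1 - x0 + 1L)
    inside <- points_in_polygon(gx, gy, poly)
    if (sum(inside) < 16L) break       # template too small at this scale
    pts <- cbind(gx[inside], gy[inside])
    idx <- pts[, 2] + 1L + pts[, 1] * nrow(img)
    grad <- raw_gradients(img)
    eps <- config$epsilon %||% max(0.1 * stats::median(grad$mag[idx]), 1e-6)
    ngf <- normalized_gradient_field(img, eps)
    levels[[l + 1L]] <- list(
      scale = s, pts = pts,
      refvec = cbind(ngf$gx[idx], ngf$gy[idx]),
      centroid = polygon_centroid(poly), eps = eps)
    if (l + 1L < config$pyramid_levels) img <- downsample2(img)
  }
  if (!length(levels)) stop_validation("template region is empty", "template")
  levels
}

frame_pyramid <- function(image, levels) {
  out <- vector("list", length(levels))
  img <- image
  for (l in seq_along(levels)) {
    out[[l]] <- raw_gradients(img)
    if (l < length(levels)) img <- downsample2(img)
  }
  out
}

# Similarity of the reference template under pose (theta, tx, ty) with one
# frame's NGF: mean squared inner product of the rotated reference vectors
# with the frame's gradient vectors. The frame's raw gradients are sampled
# bilinearly at the transformed template points and normalized afterwards
# (normalizing before interpolation shrinks off-grid vectors, which would
# bias the score toward integer-aligned poses). Pose in level units.
ngf_score <- function(theta, tx, ty, lev, ngf) {
  R <- rot2(theta)
  world <- sweep(lev$pts, 2L, lev$centroid) %*% t(R)
  wx <- world[, 1] + lev$centroid[1] + tx
  wy <- world[, 2] + lev$centroid[2] + ty
  sgx <- bilinear_sample(ngf$gx, wx, wy)
  sgy <- bilinear_sample(ngf$gy, wx, wy)
  den <- sqrt(sgx^2 + sgy^2 + lev$eps^2)
  rv <- lev$refvec %*% t(R)
  mean(((rv[, 1] * sgx + rv[, 2] * sgy) / den)^2)
}

# Grid + continuous search for one frame around `init` (level-0 pose).
# The coarsest level sweeps the full translation bound; rotation is swept
# over its full bound down to the middle levels (coarse scales alias the
# internal texture, so a coarse rotation optimum is not trusted) and only
# refined locally at the finest level. Tie-breaking: among equal best
# scores, the smallest pose change from init.
search_pose <- function(init, levels, pyr, config) {
  nl <- length(levels)
  rot_b <- config$max_rot_per_frame
  cur <- init
  for (l in rev(seq_len(nl))) {
    s <- levels[[l]]$scale
    if (l == nl) {                       # coarsest: full translation sweep
      dmax <- max(1, floor(config$max_trans_per_frame / s))
      dtr <- seq.int(-dmax, dmax) * s
    } else {
      dtr <- seq(-1, 1, by = 0.5) * s
    }
    if (l > 1L || nl == 1L) {            # full rotation range, finer steps down
      step <- if (l == nl && nl > 1L) rot_b / 4 else rot_b / 8
      dth <- seq(-rot_b, rot_b, by = step) + (init[1] - cur[1])
    } else {                             # finest: local rotation refinement
      dth <- seq(-0.75, 0.75, by = 0.25)
    }
    cand <- expand.grid(dth = dth, dx = dtr, dy = dtr, KEEP.OUT.ATTRS = FALSE)
    # order by distance from current estimate so which.max prefers the
    # smallest pose change on ties
    dist <- abs(cand$dth) + (abs(cand$dx) + abs(cand$dy)) / s
    cand <- cand[order(dist), , drop = FALSE]
    sc <- vapply(seq_len(nrow(cand)), function(i) {
      ngf_score(cur[1] + cand$dth[i], (cur[2] + cand$dx[i]) / s,
                (cur[3] + cand$dy[i]) / s, levels[[l]], pyr[[l]])
    }, numeric(1))
    b <- which.max(sc)
    cur <- c(cur[1] + cand$dth[b], cur[2] + cand$dx[b], cur[3] + cand$dy[b])
    best_score <- sc[b]
  }
  if (config$refine) {
    neg <- function(p) -ngf_score(p[1], p[2], p[3], levels[[1]], pyr[[1]])
    opt <- stats::optim(cur, neg, method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-12))
    if (-opt$value >= best_score) {
      cur <- opt$par
      best_score <- -opt$value
    }
  }
  list(pose = cur, score = best_score)
}

pose_in_bounds <- function(template, pose, w, h) {
  poly <- apply_pose(template$polygon, pose[1], pose[2], pose[3],
                     polygon_centroid(template$polygon))
  all(poly[, 1] >= 0) && all(poly[, 1] <= w - 1) &&
    all(poly[, 2] >= 0) && all(poly[, 2] <= h - 1)
}

track_frames_core <- function(frames, template, config, levels, poses, scores,
                              frame_order) {
  w <- ncol(frames[[1]]); h <- nrow(frames[[1]])
  prev <- NULL
  for (k in seq_along(frame_order)) {
    f <- frame_order[k]
    init <- if (is.null(prev)) poses[f, ] else poses[prev, ]
    pyr <- frame_pyramid(frames[[f]], levels)
    res <- search_pose(init, levels, pyr, config)
    poses[f, ] <- res$pose
    scores[f] <- res$score
    prev <- f
  }
  list(poses = poses, scores = scores)
}

#' Track one vertebra through a frame stack
#'
#' Follows the bony structure inside a template polygon through all frames
#' by best-fit rigid 2-D matching (rotation about the polygon centroid plus
#' translation) of normalized gradient field images, proceeding outward from
#' the reference frame with each search initialized at the neighboring
#' frame's pose and refined coarse-to-fine. The match score is the mean
#' squared inner product of the normalized gradient fields over the
#' transformed template region (in `[0, 1]`). A pose is flagged invalid when
#' the transformed polygon leaves the image bounds or the score falls below
#' the configured floor.
#'
#' @param frames List of grayscale matrices, 3-D array, or a
#'   [render_frames()] stack.
#' @param template A [template_area()] drawn on the reference (median) frame.
#' @param search_config A [track_config()].
#' @return An object of class `vertebra_track`: a data frame with one row
#'   per frame (`frame_index`, `vertebra_label`, `rotation_deg` relative to
#'   the reference frame, `tx_px`, `ty_px`, `match_score`, `valid`) carrying
#'   the template, configuration and an empty correction audit log as
#'   attributes.
#' @export
track_vertebra <- function(frames, template, search_config = track_config()) {
  frames <- as_frame_list(frames)
  if (!inherits(template, "template_area")) {
    stop_validation("template must be a template_area", "template")
  }
  if (!inherits(search_config, "track_config")) {
    stop_validation("search_config must be a track_config", "search_config")
  }
  n <- length(frames)
  ref <- template$reference_frame_index
  if (ref > n) stop_validation("reference frame index exceeds stack length",
                               "reference_frame_index")
  levels <- prepare_reference(frames[[ref]], template, search_config)
  poses <- matrix(0, n, 3L)
  scores <- numeric(n)

  # Reference frame: identity pose by definition; score = self-similarity.
  pyr_ref <- frame_pyramid(frames[[ref]], levels)
  scores[ref] <- ngf_score(0, 0, 0, levels[[1]], pyr_ref[[1]])

  if (ref < n) {
    r <- track_frames_core(frames, template, search_config, levels,
                           poses, scores, seq.int(ref + 1L, n))
    poses <- r$poses; scores <- r$scores
  }
  if (ref > 1L) {
    r <- track_frames_core(frames, template, search_config, levels,
                           poses, scores, seq.int(ref - 1L, 1L))
    poses <- r$poses; scores <- r$scores
  }
  finish_track(frames, template, search_config, levels, poses, scores,
               audit = empty_audit_log())
}

empty_audit_log <- function() {
  data.frame(frame_index = integer(), rotation_deg = numeric(),
             tx_px = numeric(), ty_px = numeric(),
             previous_rotation_deg = numeric(), previous_tx_px = numeric(),
             previous_ty_px = numeric(), stringsAsFactors = FALSE)
}

finish_track <- function(frames, template, config, levels, poses, scores, audit) {
  n <- length(frames)
  w <- ncol(frames[[1]]); h <- nrow(frames[[1]])
  valid <- vapply(seq_len(n), function(f) {
    pose_in_bounds(template, poses[f, ], w, h) && scores[f] >= config$min_score
  }, logical(1))
  out <- data.frame(
    frame_index = seq_len(n),
    vertebra_label = template$vertebra_label,
    rotation_deg = poses[, 1], tx_px = poses[, 2], ty_px = poses[, 3],
    match_score = scores, valid = valid, stringsAsFactors = FALSE)
  attr(out, "template") <- template
  attr(out, "config") <- config
  attr(out, "levels") <- levels
  attr(out, "audit_log") <- audit
  class(out) <- c("vertebra_track", "data.frame")
  out
}

#' Manually correct a tracked pose and re-track downstream frames
#'
#' Replaces the pose at one frame with an analyst-supplied value, re-tracks
#' all frames beyond it (in the direction away from the reference frame)
#' from the corrected initialization, and records the correction in the
#' track's audit log. A correction that jumps farther from its neighbors
#' than the per-frame search bounds triggers a warning but is still applied.
#'
#' @param track A [track_vertebra()] result.
#' @param frames The frame stack the track was computed from.
#' @param frame_index Frame to correct (1-based).
#' @param corrected_pose Numeric `c(rotation_deg, tx_px, ty_px)`.
#' @return A corrected `vertebra_track` with an updated audit log.
#' @export
manual_correction <- function(track, frames, frame_index, corrected_pose) {
  if (!inherits(track, "vertebra_track")) {
    stop_validation("track must be a vertebra_track", "track")
  }
  frames <- as_frame_list(frames)
  n <- nrow(track)
  if (frame_index < 1L || frame_index > n) {
    stop_validation("frame_index out of range", "frame_index")
  }
  corrected_pose <- as.numeric(corrected_pose)
  if (length(corrected_pose) != 3L || any(!is.finite(corrected_pose))) {
    stop_validation("corrected_pose must be c(rotation_deg, tx_px, ty_px)",
                    "corrected_pose")
  }
  template <- attr(track, "template")
  config <- attr(track, "config")
  levels <- attr(track, "levels")
  ref <- template$reference_frame_index

  neighbors <- intersect(c(frame_index - 1L, frame_index + 1L), seq_len(n))
  for (nb in neighbors) {
    nbp <- c(track$rotation_deg[nb], track$tx_px[nb], track$ty_px[nb])
    if (abs(corrected_pose[1] - nbp[1]) > config$max_rot_per_frame ||
        max(abs(corrected_pose[2:3] - nbp[2:3])) > config$max_trans_per_frame) {
      warning(sprintf(
        "correction at frame %d lies outside the search bounds of frame %d; applied anyway",
        frame_index, nb), call. = FALSE)
      break
    }
  }

  poses <- cbind(track$rotation_deg, track$tx_px, track$ty_px)
  scores <- track$match_score
  poses[frame_index, ] <- corrected_pose
  pyr <- frame_pyramid(frames[[frame_index]], levels)
  scores[frame_index] <- ngf_score(corrected_pose[1], corrected_pose[2],
                                   corrected_pose[3], levels[[1]], pyr[[1]])

  redo <- if (frame_index > ref && frame_index < n) {
    seq.int(frame_index + 1L, n)
  } else if (frame_index < ref && frame_index > 1L) {
    seq.int(frame_index - 1L, 1L)
  } else {
    integer()
  }
  if (length(redo)) {
    # seed the re-track with the corrected pose as "previous"
    prev <- frame_index
    for (f in redo) {
      init <- poses[prev, ]
      pyr <- frame_pyramid(frames[[f]], levels)
      res <- search_pose(init, levels, pyr, config)
      poses[f, ] <- res$pose
      scores[f] <- res$score
      prev <- f
    }
  }
  audit <- rbind(attr(track, "audit_log"), data.frame(
    frame_index = as.integer(frame_index),
    rotation_deg = corrected_pose[1], tx_px = corrected_pose[2],
    ty_px = corrected_pose[3],
    previous_rotation_deg = track$rotation_deg[frame_index],
    previous_tx_px = track$tx_px[frame_index],
    previous_ty_px = track$ty_px[frame_index], stringsAsFactors = FALSE))
  finish_track(frames, template, config, levels, poses, scores, audit)
}

#' Audit log of manual corrections
#'
#' @param track A [track_vertebra()] result.
#' @return Data frame with one row per applied correction.
#' @export
audit_log <- function(track) {
  if (!inherits(track, "vertebra_track")) {
    stop_validation("track must be a vertebra_track", "track")
  }
  attr(track, "audit_log")
}

#' Track all template vertebrae in a stack
#'
#' Convenience wrapper running [track_vertebra()] for every template and
#' binding the poses into one table.
#'
#' @param frames Frame stack (list, array or `phantom_stack`).
#' @param templates List of [template_area()] (or a `phantom_stack`).
#' @param search_config A [track_config()].
#' @return Data frame of poses for all vertebrae, plus a `tracks` attribute
#'   holding the individual `vertebra_track` objects.
#' @export
track_all <- function(frames, templates, search_config = track_config()) {
  if (inherits(templates, "phantom_stack")) templates <- templates$templates
  frames <- as_frame_list(frames)
  tracks <- lapply(templates, function(tp) {
    track_vertebra(frames, tp, search_config)
  })
  names(tracks) <- vapply(templates, `[[`, character(1), "vertebra_label")
  out <- do.call(rbind, lapply(tracks, as.data.frame))
  rownames(out) <- NULL
  attr(out, "tracks") <- tracks
  out
}
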