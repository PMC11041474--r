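# Pure arithmetic on poses: per-segment inter-frame rotation increments and
# cumulative block rotation (the two axes of the contribution plots).

#' Per-segment inter-frame rotation increments
#'
#' The segment rotation at frame `i` is the relative sagittal angle of the
#' upper vertebra with respect to the lower one; the increment for frame
#' pair `i` is the exact signed difference
#' `[theta_u(i+1) - theta_l(i+1)] - [theta_u(i) - theta_l(i)]`. No smoothing
#' is applied at this stage. Frame pairs touching an invalid pose are masked.
#'
#' @param upper,lower Pose tables for the two adjacent vertebrae: data frames
#'   with columns `frame_index`, `vertebra_label`, `rotation_deg` and
#'   optionally `valid` (e.g. one vertebra's rows of a pose CSV, or a
#'   [track_vertebra()] result).
#' @param extension_sign `+1` if increasing tracked rotation is anatomical
#'   extension (so extension peaks are maxima), `-1` to flip; set once per
#'   acquisition setup.
#' @return An object of class `segment_series`: list with `segment_label`,
#'   `increments_deg` (length `n_frames - 1`), `valid_mask` and `frame_pairs`.
#' @export
compute_segment_series <- function(upper, lower, extension_sign = 1) {
  for (nm in c("frame_index", "rotation_deg", "vertebra_label")) {
    if (!nm %in% names(upper) || !nm %in% names(lower)) {
      stop_validation(sprintf("pose tables need a '%s' column", nm), nm)
    }
  }
  upper <- upper[order(upper$frame_index), ]
  lower <- lower[order(lower$frame_index), ]
  if (nrow(upper) != nrow(lower) ||
      !all(upper$frame_index == lower$frame_index)) {
    stop_validation("upper and lower pose tables must cover the same frames",
                    "frame_index")
  }
  if (nrow(upper) < 2L) {
    stop_validation("at least two frames are required", "frame_index")
  }
  if (!extension_sign %in% c(-1, 1)) {
    stop_validation("extension_sign must be +1 or -1", "extension_sign")
  }
  rel <- upper$rotation_deg - lower$rotation_deg
  inc <- extension_sign * diff(rel)
  vu <- if ("valid" %in% names(upper)) upper$valid else rep(TRUE, nrow(upper))
  vl <- if ("valid" %in% names(lower)) lower$valid else rep(TRUE, nrow(lower))
  v <- vu & vl
  structure(
    list(segment_label = paste0(upper$vertebra_label[1], lower$vertebra_label[1]),
         increments_deg = inc,
         valid_mask = v[-length(v)] & v[-1L],
         frame_pairs = seq_len(length(inc))),
    class = "segment_series"
  )
}

#' Build all adjacent-segment series from a pose table
#'
#' @param poses Pose table covering several vertebrae (columns as in
#'   [compute_segment_series()]).
#' @param vertebra_order Cranial-to-caudal vertebra labels; consecutive pairs
#'   define the segments.
#' @param extension_sign See [compute_segment_series()].
#' @return Named list of `segment_series`, one per adjacent pair.
#' @export
segment_series_from_poses <- function(poses,
                                      vertebra_order = c("L1", "L2", "L3",
                                                         "L4", "L5", "S1"),
                                      extension_sign = 1) {
  missing <- setdiff(vertebra_order, unique(poses$vertebra_label))
  if (length(missing)) {
    stop_validation(sprintf("poses lack vertebrae: %s",
                            paste(missing, collapse = ", ")), "vertebra_label")
  }
  out <- list()
  for (i in seq_len(length(vertebra_order) - 1L)) {
    up <- poses[poses$vertebra_label == vertebra_order[i], ]
    lo <- poses[poses$vertebra_label == vertebra_order[i + 1L], ]
    s <- compute_segment_series(up, lo, extension_sign)
    out[[s$segment_label]] <- s
  }
  out
}

#' Cumulative block rotation
#'
#' Running sum over frame pairs of the summed increments of a block of
#' segments; the x-axis against which segment contributions are plotted.
#'
#' @param series_list Named list of `segment_series` sharing a frame count.
#' @param block_labels Segments to sum; default all segments in
#'   `series_list` (e.g. L1-S1), alternatively an upper block such as
#'   `c("L1L2", "L2L3", "L3L4")` for L1-L4.
#' @return An object of class `cumulative_axis`: list with `block_labels`,
#'   `values_deg` (per frame pair) and `valid_mask`.
#' @export
compute_cumulative <- function(series_list, block_labels = NULL) {
  if (!length(series_list)) stop_validation("series_list is empty", "series_list")
  labs <- vapply(series_list, `[[`, character(1), "segment_label")
  names(series_list) <- labs
  block_labels <- block_labels %||% labs
  absent <- setdiff(block_labels, labs)
  if (length(absent)) {
    stop_validation(sprintf("block segment(s) absent: %s",
                            paste(absent, collapse = ", ")), "block_labels")
  }
  lens <- vapply(series_list, function(s) length(s$increments_deg), integer(1))
  if (length(unique(lens)) != 1L) {
    stop_validation("all series must share the same frame count", "series_list")
  }
  inc <- rowSums(vapply(block_labels,
                        function(b) series_list[[b]]$increments_deg,
                        numeric(lens[1])))
  vm <- Reduce(`&`, lapply(block_labels, function(b) series_list[[b]]$valid_mask))
  structure(
    list(block_labels = block_labels, values_deg = cumsum(inc),
         valid_mask = vm),
    class = "cumulative_axis"
  )
}

#' Split a recording into extension-flexion-extension phases
#'
#' Finds the two turning points of the (lightly smoothed) cumulative block
#' rotation — the global maximum followed by the subsequent global minimum —
#' and returns the frame-pair index windows of the three phases. A 3-point
#' running median resists single-frame noise; boundary ties resolve to the
#' earliest frame.
#'
#' @param cumulative A [compute_cumulative()] result covering the full
#'   recording.
#' @return List of class `phase_windows` with integer index vectors
#'   `extension1`, `flexion`, `extension2` and element `boundaries`.
#' @export
split_phases <- function(cumulative) {
  if (!inherits(cumulative, "cumulative_axis")) {
    stop_validation("cumulative must be a cumulative_axis", "cumulative")
  }
  v <- cumulative$values_deg
  m <- length(v)
  if (m < 5L) stop_validation("cumulative series too short for a cycle",
                              "cumulative")
  sm <- stats::runmed(v, k = 3L, endrule = "keep")
  # The flexion bottom is the unique global minimum of a full cycle; anchor
  # on it first, then take the preceding maximum as the end of extension1.
  # The median filter locates each turning point robustly but flattens
  # single-frame extrema, so the exact index is refined on the raw series
  # within one frame pair of the smoothed optimum.
  # which.min/which.max pick the earliest index on ties.
  refine <- function(i, f) {
    win <- max(1L, i - 1L):min(m, i + 1L)
    win[f(v[win])]
  }
  i2 <- refine(which.min(sm), which.min)
  if (i2 >= m || i2 <= 2L) {
    stop_validation("cumulative rotation has no turning point; recording is not a full extension-flexion-extension cycle",
                    "cumulative")
  }
  i1 <- refine(which.max(sm[seq_len(i2 - 1L)]), which.max)
  if (i1 <= 1L || i1 >= i2) {
    stop_validation("no initial extension turning point found; recording is not a full cycle",
                    "cumulative")
  }
  structure(
    list(extension1 = seq_len(i1),
         flexion = seq.int(i1 + 1L, i2),
         extension2 = seq.int(i2 + 1L, m),
         boundaries = c(i1, i2)),
    class = "phase_windows"
  )
}

#' @export
print.phase_windows <- function(x, ...) {
  cat(sprintf("Phases (frame pairs): extension1 1-%d, flexion %d-%d, extension2 %d-%d\n",
              x$boundaries[1], x$boundaries[1] + 1L, x$boundaries[2],
              x$boundaries[2] + 1L,
              x$boundaries[2] + length(x$extension2)))
  invisible(x)
}
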