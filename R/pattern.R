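# Contribution-curve machinery: Gaussian low-pass smoothing of increment
# series, thresholded peak detection, and classification of the segmental
# contribution sequence against the canonical late-extension pattern.

# Symmetric (edge-repeating) reflection of out-of-range indices into 1..m.
reflect_index <- function(i, m) {
  j <- ((i - 1L) %% (2L * m) + 2L * m) %% (2L * m)
  ifelse(j < m, j + 1L, 2L * m - j)
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k / sum(k)                           # unit DC gain, exactly
}

#' Gaussian low-pass smoothing of a contribution series
#'
#' Discrete Gaussian convolution with symmetric-reflection boundary handling
#' and a kernel normalized to unit sum, so a constant series is reproduced
#' exactly. `sigma` is expressed in frame-pair units.
#'
#' @param series A `segment_series`, a `contribution_curve`, or a numeric
#'   vector of increments (degrees per frame pair).
#' @param sigma Positive Gaussian standard deviation in frame-pair units;
#'   the default of 2 suppresses single-frame noise while preserving peaks
#'   near the 0.3 degree retention threshold at typical pulse rates.
#' @param x Optional cumulative-rotation coordinate of the same length.
#' @return An object of class `contribution_curve`: list with
#'   `segment_label`, `x`, `y` (smoothed increments), `smoothing_sigma`,
#'   `valid`.
#' @export
#' @examples
#' smooth_curve(c(0, 0, 1, 0, 0), sigma = 1)$y
smooth_curve <- function(series, sigma = 2, x = NULL) {
  label <- NA_character_
  valid <- TRUE
  if (inherits(series, "segment_series")) {
    label <- series$segment_label
    valid <- all(series$valid_mask)
    y <- series$increments_deg
  } else if (inherits(series, "contribution_curve")) {
    label <- series$segment_label
    valid <- series$valid
    x <- x %||% series$x
    y <- series$y
  } else {
    y <- as.numeric(series)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop_validation("sigma must be a single positive number", "sigma")
  }
  m <- length(y)
  if (m < 3L) stop_validation("series must have at least 3 values", "series")
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  padded <- y[reflect_index(seq.int(1L - r, m + r), m)]
  sm <- stats::filter(padded, k, method = "convolution", sides = 2L)
  y_s <- as.numeric(sm[(r + 1L):(r + m)])
  if (!is.null(x) && length(x) != m) {
    stop_validation("x must match the series length", "x")
  }
  structure(
    list(segment_label = label, x = x, y = y_s, smoothing_sigma = sigma,
         valid = valid),
    class = "contribution_curve"
  )
}

#' Contribution curves of a block within one movement phase
#'
#' Restricts each segment's increment series to one phase, orients it so
#' that motion in the phase direction is positive (flexion increments are
#' negated and the cumulative axis is measured as flexion progress), applies
#' Gaussian smoothing within the phase, and attaches the cumulative block
#' rotation as the x coordinate.
#'
#' @param series_list Named list of `segment_series` (see
#'   [segment_series_from_poses()]).
#' @param cumulative A [compute_cumulative()] result for the plotting block.
#' @param phases A [split_phases()] result.
#' @param phase `"extension2"` (default; the return to maximum extension),
#'   `"flexion"` or `"extension1"`.
#' @param sigma Smoothing sigma in frame-pair units.
#' @param block_labels Segments to build curves for; default the canonical
#'   upper block present in `series_list`.
#' @return Object of class `contribution_curves`: named list of
#'   `contribution_curve`, with the phase name as attribute.
#' @export
contribution_curves <- function(series_list, cumulative, phases,
                                phase = c("extension2", "flexion", "extension1"),
                                sigma = 2,
                                block_labels = NULL) {
  phase <- match.arg(phase)
  labs <- vapply(series_list, `[[`, character(1), "segment_label")
  names(series_list) <- labs
  block_labels <- block_labels %||% intersect(c("L1L2", "L2L3", "L3L4"), labs)
  absent <- setdiff(block_labels, labs)
  if (length(absent)) {
    stop_validation(sprintf("block segment(s) absent: %s",
                            paste(absent, collapse = ", ")), "block_labels")
  }
  idx <- phases[[phase]]
  v <- cumulative$values_deg
  x <- if (phase == "flexion") {
    start <- if (idx[1] > 1L) v[idx[1] - 1L] else 0
    start - v[idx]                      # flexion progress, increasing
  } else {
    v[idx]
  }
  sign_y <- if (phase == "flexion") -1 else 1
  curves <- lapply(block_labels, function(b) {
    s <- series_list[[b]]
    cc <- smooth_curve(sign_y * s$increments_deg[idx], sigma = sigma, x = x)
    cc$segment_label <- b
    cc$valid <- all(s$valid_mask[idx])
    cc
  })
  names(curves) <- block_labels
  structure(curves, class = "contribution_curves", phase = phase)
}

#' Detect thresholded contribution peaks
#'
#' Finds strict local maxima of a smoothed contribution curve (plateaus are
#' resolved to their midpoint) and retains those whose height reaches the
#' measurement-error threshold; lower peaks are deemed to fall within the
#' measurement error and are discarded. Only the ordering of retained peaks
#' matters downstream; heights are kept for thresholding and reporting.
#'
#' @param curve A [smooth_curve()] result (or numeric vector).
#' @param threshold Retention threshold in degrees per frame pair
#'   (default 0.3).
#' @return Data frame of class `peak_events` with columns `segment_label`,
#'   `index` (frame pair within the curve), `position` (cumulative rotation
#'   at the peak; `NA` if the curve has no x) and `height`, ordered by
#'   increasing position.
#' @export
detect_peaks <- function(curve, threshold = 0.3) {
  if (inherits(curve, "contribution_curve")) {
    y <- curve$y; x <- curve$x; label <- curve$segment_label
  } else {
    y <- as.numeric(curve); x <- NULL; label <- NA_character_
  }
  if (threshold < 0) stop_validation("threshold must be non-negative", "threshold")
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nruns <- length(r$values)
  idx <- integer(); hts <- numeric()
  if (nruns >= 3L) {
    for (j in 2:(nruns - 1L)) {
      if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L]) {
        mid <- starts[j] + (r$lengths[j] - 1L) %/% 2L
        idx <- c(idx, mid); hts <- c(hts, r$values[j])
      }
    }
  }
  keep <- hts >= threshold
  idx <- idx[keep]; hts <- hts[keep]
  out <- data.frame(
    segment_label = rep(label, length(idx)),
    index = idx,
    position = if (is.null(x)) rep(NA_real_, length(idx)) else x[idx],
    height = hts, stringsAsFactors = FALSE)
  ord <- order(if (is.null(x)) out$index else out$position)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_events", "data.frame")
  out
}

#' Classify the segmental contribution sequence of one phase
#'
#' A recording matches the canonical pattern when, within the last-phase
#' window of the cumulative rotation range, every canonical segment shows at
#' least one retained peak and the *last* retained peak of each segment
#' occurs in canonical order (default: L3L4 before L2L3 before L1L2).
#' Position ties break toward non-match. Recordings with any invalid curve
#' (e.g. a vertebra lost from the field of view) are excluded rather than
#' classified.
#'
#' @param curves A [contribution_curves()] result (or named list of curves).
#' @param phase Phase label for reporting; defaults to the curves' phase.
#' @param canonical_pattern Ordered canonical segment labels.
#' @param last_phase_fraction Fraction of the phase's cumulative rotation
#'   range, counted from its end, inside which the canonical peaks must lie;
#'   in `(0, 1]`. The default 1 analyzes the whole phase and relies on the
#'   last-peak-per-segment rule to capture the terminal ordering.
#' @param peak_threshold Peak retention threshold in degrees.
#' @return Object of class `sequence_classification`: list with `phase`,
#'   `ordered_peaks` (all retained peaks by position), `window`,
#'   `matches_canonical`, `canonical_pattern`, `excluded`.
#' @export
classify_sequence <- function(curves, phase = NULL,
                              canonical_pattern = c("L3L4", "L2L3", "L1L2"),
                              last_phase_fraction = 1,
                              peak_threshold = 0.3) {
  if (!is.list(curves) || !length(curves)) {
    stop_validation("curves must be a non-empty list of contribution curves",
                    "curves")
  }
  phase <- phase %||% attr(curves, "phase") %||% NA_character_
  if (!is.numeric(last_phase_fraction) || last_phase_fraction <= 0 ||
      last_phase_fraction > 1) {
    stop_validation("last_phase_fraction must be in (0, 1]", "last_phase_fraction")
  }
  labs <- vapply(curves, `[[`, character(1), "segment_label")
  names(curves) <- labs
  absent <- setdiff(canonical_pattern, labs)
  if (length(absent)) {
    stop_validation(sprintf("canonical segment(s) missing from curves: %s",
                            paste(absent, collapse = ", ")), "canonical_pattern")
  }
  if (any(!vapply(curves, `[[`, logical(1), "valid"))) {
    out <- list(phase = phase, ordered_peaks = NULL, window = c(NA_real_, NA_real_),
                last_phase_fraction = last_phase_fraction,
                matches_canonical = NA, canonical_pattern = canonical_pattern,
                excluded = TRUE)
    class(out) <- "sequence_classification"
    return(out)
  }
  xr <- range(unlist(lapply(curves, `[[`, "x")))
  wstart <- xr[2] - last_phase_fraction * (xr[2] - xr[1])
  window <- c(wstart, xr[2])

  peaks <- do.call(rbind, lapply(curves, detect_peaks, threshold = peak_threshold))
  if (!is.null(peaks) && nrow(peaks)) {
    peaks <- peaks[order(peaks$position, peaks$index), , drop = FALSE]
    rownames(peaks) <- NULL
  }

  last_pos <- vapply(canonical_pattern, function(s) {
    p <- peaks[peaks$segment_label == s & peaks$position >= wstart, , drop = FALSE]
    if (!nrow(p)) NA_real_ else max(p$position)
  }, numeric(1))
  matches <- !anyNA(last_pos) && all(diff(last_pos) > 0)  # ties -> non-match

  out <- list(phase = phase, ordered_peaks = peaks, window = window,
              last_phase_fraction = last_phase_fraction,
              matches_canonical = matches,
              canonical_pattern = canonical_pattern, excluded = FALSE)
  class(out) <- "sequence_classification"
  out
}

#' @export
print.sequence_classification <- function(x, ...) {
  if (isTRUE(x$excluded)) {
    cat("Sequence classification: EXCLUDED (invalid tracking)\n")
    return(invisible(x))
  }
  cat(sprintf("Sequence classification (%s phase)\n", x$phase))
  cat(sprintf("  window: %.2f to %.2f deg cumulative (last %.0f%% of range)\n",
              x$window[1], x$window[2], 100 * x$last_phase_fraction))
  cat(sprintf("  canonical pattern %s: %s\n",
              paste(x$canonical_pattern, collapse = " -> "),
              if (isTRUE(x$matches_canonical)) "MATCH" else "no match"))
  if (!is.null(x$ordered_peaks) && nrow(x$ordered_peaks)) {
    cat("  retained peaks (by position):\n")
    print(format(x$ordered_peaks, digits = 3), row.names = FALSE)
  } else {
    cat("  no retained peaks\n")
  }
  invisible(x)
}

#' Cohort consistency of the segmental contribution sequence
#'
#' Summarizes per-recording classifications across participants and time
#' points: the fraction classified canonical per time point and overall, the
#' participants canonical at every time point, and a cohort-level
#' consistency flag (a consistent motion pattern being defined as the same
#' pattern in at least 80 percent of the recordings at each of the two time
#' points). Excluded recordings are counted but not analyzable.
#'
#' @param classifications Data frame with columns `participant`,
#'   `time_point`, `matches_canonical` (logical; `NA` for excluded) and
#'   optionally `excluded` (logical).
#' @param consistency_threshold Minimum canonical fraction per time point
#'   for the cohort flag (default 0.80).
#' @return Object of class `consistency_summary`: list with `per_time_point`
#'   (data frame: time_point, n_analyzable, n_canonical, fraction_pct),
#'   `overall` (list: n, n_canonical, fraction_pct), `consistent_participants`,
#'   `n_excluded`, `cohort_consistent`.
#' @export
consistency_summary <- function(classifications, consistency_threshold = 0.80) {
  df <- as.data.frame(classifications)
  if (!nrow(df)) stop_validation("classifications is empty", "classifications")
  for (nm in c("participant", "time_point", "matches_canonical")) {
    if (!nm %in% names(df)) {
      stop_validation(sprintf("classifications need a '%s' column", nm), nm)
    }
  }
  if (!"excluded" %in% names(df)) df$excluded <- is.na(df$matches_canonical)
  df$excluded <- df$excluded | is.na(df$matches_canonical)
  ana <- df[!df$excluded, , drop = FALSE]
  if (!nrow(ana)) stop_validation("no analyzable recordings", "classifications")

  tps <- sort(unique(df$time_point))
  per_tp <- do.call(rbind, lapply(tps, function(tp) {
    a <- ana[ana$time_point == tp, , drop = FALSE]
    data.frame(time_point = tp, n_analyzable = nrow(a),
               n_canonical = sum(a$matches_canonical),
               fraction_pct = 100 * sum(a$matches_canonical) / max(nrow(a), 1L),
               stringsAsFactors = FALSE)
  }))
  overall <- list(n = nrow(ana), n_canonical = sum(ana$matches_canonical),
                  fraction_pct = 100 * sum(ana$matches_canonical) / nrow(ana))
  consistent <- vapply(unique(df$participant), function(p) {
    rows <- df[df$participant == p, , drop = FALSE]
    all(tps %in% rows$time_point) && !any(rows$excluded) &&
      all(rows$matches_canonical)
  }, logical(1))
  structure(
    list(per_time_point = per_tp, overall = overall,
         consistent_participants = unique(df$participant)[consistent],
         n_participants = length(unique(df$participant)),
         n_excluded = sum(df$excluded),
         cohort_consistent = all(per_tp$fraction_pct >= 100 * consistency_threshold)),
    class = "consistency_summary"
  )
}

#' @export
print.consistency_summary <- function(x, ...) {
  cat("Segmental contribution sequence consistency\n")
  for (i in seq_len(nrow(x$per_time_point))) {
    r <- x$per_time_point[i, ]
    cat(sprintf("  %s: %d/%d canonical (%.0f%%)\n", r$time_point,
                r$n_canonical, r$n_analyzable, r$fraction_pct))
  }
  cat(sprintf("  overall: %d/%d canonical (%.0f%%), %d excluded\n",
              x$overall$n_canonical, x$overall$n, x$overall$fraction_pct,
              x$n_excluded))
  cat(sprintf("  participants canonical at all time points: %d/%d (%s)\n",
              length(x$consistent_participants), x$n_participants,
              paste(x$consistent_participants, collapse = ", ")))
  cat(sprintf("  cohort-level consistency: %s\n",
              if (x$cohort_consistent) "yes" else "no"))
  invisible(x)
}

#' Plot contribution curves
#'
#' Draws each segment's smoothed inter-frame rotation against the cumulative
#' block rotation, with the retention threshold as a reference line — the
#' standard reading plot for the contribution sequence.
#'
#' @param x A [contribution_curves()] result.
#' @param threshold Peak retention threshold to mark (degrees).
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.contribution_curves <- function(x, threshold = 0.3, ...) {
  xs <- x[[1]]$x
  ys <- vapply(x, `[[`, numeric(length(xs)), "y")
  graphics::matplot(xs, ys, type = "l", lty = 1, lwd = 2,
                    col = seq_along(x) + 1L,
                    xlab = "cumulative block rotation (deg)",
                    ylab = "rotation between successive frames (deg)",
                    main = sprintf("Segmental contribution (%s)",
                                   attr(x, "phase") %||% ""), ...)
  graphics::abline(h = threshold, lty = 3)
  graphics::legend("topleft", legend = names(x), col = seq_along(x) + 1L,
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}
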