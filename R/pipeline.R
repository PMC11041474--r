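# Orchestration: a single config object carrying every tunable default, a
# simulate entry point writing interchange files, per-recording analysis,
# and a cohort-level report (classification fractions + reliability).

#' Pipeline configuration
#'
#' Gathers every tunable parameter of the simulate - track - kinematics -
#' pattern - reliability pipeline; all numeric defaults used in reports
#' trace back to a field of this object.
#'
#' @param seed Integer seed for every stochastic stage.
#' @param protocol A [motion_protocol()].
#' @param kinematics A [segment_kinematics_spec()].
#' @param geometry A [phantom_geometry()] for rendering.
#' @param tracker A [track_config()].
#' @param smoothing_sigma Gaussian smoothing sigma, frame-pair units.
#' @param peak_threshold Peak retention threshold, degrees (default 0.3).
#' @param last_phase_fraction See [classify_sequence()].
#' @param cumulative_block Segments summed for the cumulative axis; `NULL`
#'   means all segments (L1-S1).
#' @param pattern_block Segments whose curves enter the classification
#'   (default the upper block L1-L4, i.e. L1L2, L2L3, L3L4).
#' @param canonical_pattern Ordered canonical segment labels.
#' @param phase Phase classified (default `"extension2"`, the return to
#'   maximum extension); flexion is analyzed separately.
#' @param icc_type `"consistency"` or `"agreement"`.
#' @param extension_sign +1 or -1; see [compute_segment_series()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            protocol = motion_protocol(),
                            kinematics = segment_kinematics_spec(),
                            geometry = phantom_geometry(),
                            tracker = track_config(),
                            smoothing_sigma = 2,
                            peak_threshold = 0.3,
                            last_phase_fraction = 1,
                            cumulative_block = NULL,
                            pattern_block = c("L1L2", "L2L3", "L3L4"),
                            canonical_pattern = c("L3L4", "L2L3", "L1L2"),
                            phase = "extension2",
                            icc_type = "consistency",
                            extension_sign = 1) {
  if (peak_threshold < 0) {
    stop_validation("peak_threshold must be non-negative", "peak_threshold")
  }
  if (smoothing_sigma <= 0) {
    stop_validation("smoothing_sigma must be positive", "smoothing_sigma")
  }
  structure(
    list(seed = as.integer(seed), protocol = protocol, kinematics = kinematics,
         geometry = geometry, tracker = tracker,
         smoothing_sigma = smoothing_sigma, peak_threshold = peak_threshold,
         last_phase_fraction = last_phase_fraction,
         cumulative_block = cumulative_block, pattern_block = pattern_block,
         canonical_pattern = canonical_pattern, phase = phase,
         icc_type = match.arg(icc_type, c("consistency", "agreement")),
         extension_sign = extension_sign),
    class = "pipeline_config"
  )
}

#' Write and read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `path`, invisibly; `read_config` returns the reconstructed
#'   `pipeline_config` (lossless round trip up to numeric representation).
#' @export
write_config <- function(config, path) {
  if (!inherits(config, "pipeline_config")) {
    stop_validation("config must be a pipeline_config", "config")
  }
  plain <- rapply(unclass(config), function(x) x, how = "replace")
  plain$protocol <- unclass(config$protocol)
  plain$protocol$phase_plan <- as.list(config$protocol$phase_plan)
  plain$kinematics <- unclass(config$kinematics)
  plain$geometry <- unclass(config$geometry)
  plain$tracker <- unclass(config$tracker)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("config file '%s' not found", path))
  y <- yaml::read_yaml(path)
  pipeline_config(
    seed = y$seed,
    protocol = motion_protocol(y$protocol$duration_s, y$protocol$frame_rate_hz,
                               y$protocol$n_frames,
                               unlist(y$protocol$phase_plan),
                               y$protocol$start_u %||% 0.5),
    kinematics = do.call(segment_kinematics_spec,
                         lapply(y$kinematics, unlist)),
    geometry = do.call(phantom_geometry,
                       lapply(y$geometry, function(v)
                         if (is.list(v)) unlist(v) else v)),
    tracker = do.call(track_config, y$tracker),
    smoothing_sigma = y$smoothing_sigma,
    peak_threshold = y$peak_threshold,
    last_phase_fraction = y$last_phase_fraction,
    cumulative_block = unlist(y$cumulative_block),
    pattern_block = unlist(y$pattern_block),
    canonical_pattern = unlist(y$canonical_pattern),
    phase = y$phase, icc_type = y$icc_type,
    extension_sign = y$extension_sign
  )
}

#' Simulate a recording bundle on disk
#'
#' Generates ground-truth kinematics (and optionally rendered frames with
#' their template polygons) and writes the interchange files the later
#' stages read: `ground_truth.csv`, `poses.csv` (reported, noise-added
#' poses), and with `render = TRUE` a frame stack plus `templates.json`.
#' Deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param render Also render and write the phantom frame stack.
#' @param format Frame format, `"tiff"` or `"png"`.
#' @return Invisibly, a list with the generated `recording`, optional
#'   `stack`, and output `paths`.
#' @export
run_simulate <- function(config = pipeline_config(), out_dir,
                         render = FALSE, format = c("tiff", "png")) {
  format <- match.arg(format)
  ok <- try(dir.create(out_dir, showWarnings = FALSE, recursive = TRUE),
            silent = TRUE)
  if (inherits(ok, "try-error") || !dir.exists(out_dir)) {
    stop_io(sprintf("cannot create output directory '%s'", out_dir))
  }
  rec <- generate_kinematics(config$kinematics, config$protocol, config$seed)
  paths <- list(ground_truth = file.path(out_dir, "ground_truth.csv"),
                poses = file.path(out_dir, "poses.csv"))
  write_poses_csv(as_poses(rec, noisy = TRUE), paths$poses)
  stack <- NULL
  if (render) {
    stack <- render_frames(rec, config$geometry, seed = config$seed)
    paths$frames <- if (format == "tiff") {
      file.path(out_dir, "frames.tif")
    } else {
      file.path(out_dir, "frames")
    }
    write_frames(stack, paths$frames, format)
    paths$templates <- file.path(out_dir, "templates.json")
    write_templates_json(stack, paths$templates)
  }
  write_ground_truth_csv(rec, paths$ground_truth, stack)
  invisible(list(recording = rec, stack = stack, paths = paths))
}

#' Analyze one recording's pose table
#'
#' Runs the kinematics and pattern stages: segment series, cumulative block
#' rotation, phase splitting, per-phase contribution curves and sequence
#' classification. A recording in which any pose is flagged invalid (e.g. a
#' vertebra left the field of view) is excluded rather than classified.
#'
#' @param poses Pose table (see [read_poses_csv()]).
#' @param config A [pipeline_config()].
#' @return A [classify_sequence()] result, with the contribution curves and
#'   phase windows attached as attributes (`NULL`s when excluded).
#' @export
analyze_recording <- function(poses, config = pipeline_config()) {
  spec <- config$kinematics
  uppers <- substr(spec$segment_labels, 1L, 2L)
  vert_order <- c(uppers, substr(spec$segment_labels[length(spec$segment_labels)],
                                 3L, 4L))
  if ("valid" %in% names(poses) && any(!poses$valid)) {
    out <- list(phase = config$phase, ordered_peaks = NULL,
                window = c(NA_real_, NA_real_),
                last_phase_fraction = config$last_phase_fraction,
                matches_canonical = NA,
                canonical_pattern = config$canonical_pattern, excluded = TRUE)
    class(out) <- "sequence_classification"
    return(out)
  }
  series <- segment_series_from_poses(poses, vert_order, config$extension_sign)
  cum_all <- compute_cumulative(series, config$cumulative_block)
  phases <- split_phases(cum_all)
  cum_block <- compute_cumulative(series, config$pattern_block)
  curves <- contribution_curves(series, cum_block, phases,
                                phase = config$phase,
                                sigma = config$smoothing_sigma,
                                block_labels = config$pattern_block)
  cls <- classify_sequence(curves, phase = config$phase,
                           canonical_pattern = config$canonical_pattern,
                           last_phase_fraction = config$last_phase_fraction,
                           peak_threshold = config$peak_threshold)
  attr(cls, "curves") <- curves
  attr(cls, "phases") <- phases
  cls
}

#' Run the full cohort pipeline
#'
#' Classifies every recording of a cohort and summarizes consistency across
#' time points; when a second rater's poses are supplied, per-(segment,
#' recording) two-way mixed ICCs and their per-segment means are added.
#' Recordings with field-of-view loss are excluded and counted.
#'
#' @param manifest Data frame with one row per recording: columns
#'   `participant`, `time_point`, and either a `poses` list-column of pose
#'   tables or a `poses_csv` path column; optionally `rater2_csv` (or a
#'   `poses_rater2` list-column) for reliability.
#' @param config A [pipeline_config()].
#' @return Object of class `cohort_report`: list with `classifications`
#'   (data frame), `summary` ([consistency_summary()]), `icc` (an
#'   [segment_icc_summary()] or `NULL`) and `config`.
#' @export
run_full <- function(manifest, config = pipeline_config()) {
  manifest <- as.data.frame(manifest)
  if (!nrow(manifest)) stop_validation("manifest is empty", "manifest")
  for (nm in c("participant", "time_point")) {
    if (!nm %in% names(manifest)) {
      stop_validation(sprintf("manifest needs a '%s' column", nm), nm)
    }
  }
  get_poses <- function(i, col_list, col_csv) {
    if (col_list %in% names(manifest)) return(manifest[[col_list]][[i]])
    if (col_csv %in% names(manifest)) {
      p <- manifest[[col_csv]][i]
      if (is.na(p) || !nzchar(p)) return(NULL)
      return(read_poses_csv(p))
    }
    NULL
  }
  rows <- list(); icc_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    rid <- sprintf("%s-%s", manifest$participant[i], manifest$time_point[i])
    poses <- get_poses(i, "poses", "poses_csv")
    if (is.null(poses)) {
      stop_validation(sprintf("manifest row %d (%s) has no poses", i, rid),
                      "poses")
    }
    cls <- tryCatch(analyze_recording(poses, config), error = function(e) {
      stop_validation(sprintf("[pattern stage, recording %s] %s", rid,
                              conditionMessage(e)))
    })
    rows[[i]] <- data.frame(
      participant = manifest$participant[i],
      time_point = manifest$time_point[i],
      phase = config$phase,
      matches_canonical = cls$matches_canonical,
      excluded = cls$excluded, stringsAsFactors = FALSE)

    poses2 <- get_poses(i, "poses_rater2", "rater2_csv")
    if (!is.null(poses2) && !cls$excluded) {
      spec <- config$kinematics
      vo <- c(substr(spec$segment_labels, 1L, 2L),
              substr(spec$segment_labels[length(spec$segment_labels)], 3L, 4L))
      ratings <- ratings_from_poses(poses, poses2, vo, config$extension_sign)
      icc_rows[[length(icc_rows) + 1L]] <- do.call(rbind, lapply(
        names(ratings), function(b) {
          data.frame(segment_label = b, recording_id = rid,
                     icc_value = icc_two_way_mixed(ratings[[b]],
                                                   type = config$icc_type)$icc_value,
                     stringsAsFactors = FALSE)
        }))
    }
  }
  classifications <- do.call(rbind, rows)
  summary <- consistency_summary(classifications)
  icc <- if (length(icc_rows)) {
    segment_icc_summary(do.call(rbind, icc_rows))
  } else NULL
  structure(list(classifications = classifications, summary = summary,
                 icc = icc, config = config),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report: %d recordings (%d excluded), phase %s\n",
              nrow(x$classifications), sum(x$classifications$excluded),
              x$config$phase))
  print(x$summary)
  if (!is.null(x$icc)) print(x$icc)
  invisible(x)
}

#' Example cohort classification table
#'
#' A bundled 11-participant, two-time-point example of classification
#' bookkeeping: recording P1-T1 is excluded (vertebra out of the field of
#' view), participants P5 and P7 are non-canonical at both time points, and
#' at T2 two further recordings (P9 and one additional participant) are
#' non-canonical, giving 8/10 canonical at T1, 7/11 at T2 and 15/21 overall.
#'
#' @return Data frame with columns `participant`, `time_point`,
#'   `matches_canonical`, `excluded`.
#' @export
example_cohort_classifications <- function() {
  participants <- paste0("P", 1:11)
  df <- expand.grid(participant = participants,
                    time_point = c("T1", "T2"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$excluded <- df$participant == "P1" & df$time_point == "T1"
  non_canonical <- (df$participant %in% c("P5", "P7")) |
    (df$participant %in% c("P9", "P11") & df$time_point == "T2")
  df$matches_canonical <- ifelse(df$excluded, NA, !non_canonical)
  df[order(df$participant, df$time_point), c("participant", "time_point",
                                             "matches_canonical", "excluded")]
}
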