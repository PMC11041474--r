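# Inter-rater reliability of tracked segmental rotations: two-way mixed
# intraclass correlation from the explicit ANOVA mean-square decomposition.

#' Two-way mixed intraclass correlation coefficient
#'
#' Single-measure ICC from the two-way (targets x raters) ANOVA
#' decomposition with fixed raters. The default consistency form is
#' `ICC(3,1) = (MS_rows - MS_error) / (MS_rows + (k - 1) MS_error)`, which is
#' invariant to a constant offset between raters; the absolute-agreement
#' variant additionally penalizes rater mean differences through the column
#' mean square.
#'
#' @param values n x k numeric matrix (or data frame) of measurements:
#'   n targets (e.g. frame-pair segmental rotations of one segment in one
#'   recording) rated by k analysts. No missing cells; `n >= 3`, `k >= 2`.
#' @param type `"consistency"` (default) or `"agreement"`.
#' @param adequacy_threshold ICC value strictly above which reliability is
#'   deemed adequate (default 0.60).
#' @return Object of class `icc_fit`: list with `icc_value`, `type`, `n`,
#'   `k`, mean squares `MSR`, `MSC`, `MSE`, and `adequate`.
#' @export
#' @examples
#' x <- cbind(rater1 = 1:10, rater2 = 1:10 + 0.5)
#' icc_two_way_mixed(x)$icc_value  # offset-invariant: exactly 1
icc_two_way_mixed <- function(values, type = c("consistency", "agreement"),
                              adequacy_threshold = 0.60) {
  type <- match.arg(type)
  x <- as.matrix(values)
  if (!is.numeric(x)) stop_validation("values must be numeric", "values")
  if (anyNA(x)) stop_validation("values must have no missing cells", "values")
  n <- nrow(x); k <- ncol(x)
  if (n < 3L) stop_validation("at least 3 targets are required", "values")
  if (k < 2L) stop_validation("at least 2 raters are required", "values")

  g <- mean(x)
  rm_ <- rowMeans(x)
  cm_ <- colMeans(x)
  SSR <- k * sum((rm_ - g)^2)
  SSC <- n * sum((cm_ - g)^2)
  SST <- sum((x - g)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))

  icc <- switch(type,
    consistency = (MSR - MSE) / (MSR + (k - 1) * MSE),
    agreement = (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)))

  structure(
    list(icc_value = icc, type = type, n = n, k = k,
         MSR = MSR, MSC = MSC, MSE = MSE,
         adequacy_threshold = adequacy_threshold,
         adequate = is.finite(icc) && icc > adequacy_threshold),
    class = "icc_fit"
  )
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf("Two-way mixed ICC (%s, single measures): %.3f  [n = %d, k = %d] %s\n",
              x$type, x$icc_value, x$n, x$k,
              if (x$adequate) "adequate" else "inadequate"))
  invisible(x)
}

#' Ratings table from two raters' pose tables
#'
#' Builds the per-segment n x 2 ratings matrices feeding the ICC: the
#' measurement unit is one frame pair's segmental rotation, measured
#' independently by each analyst on the same recording.
#'
#' @param poses_rater1,poses_rater2 Pose tables covering the same frames and
#'   vertebrae (see [read_poses_csv()]).
#' @param vertebra_order Cranial-to-caudal vertebra labels.
#' @param extension_sign See [compute_segment_series()].
#' @return Named list (one element per segment) of n x 2 matrices.
#' @export
ratings_from_poses <- function(poses_rater1, poses_rater2,
                               vertebra_order = c("L1", "L2", "L3", "L4",
                                                  "L5", "S1"),
                               extension_sign = 1) {
  s1 <- segment_series_from_poses(poses_rater1, vertebra_order, extension_sign)
  s2 <- segment_series_from_poses(poses_rater2, vertebra_order, extension_sign)
  if (!identical(names(s1), names(s2))) {
    stop_validation("rater pose tables cover different segments", "poses_rater2")
  }
  out <- lapply(names(s1), function(b) {
    cbind(rater1 = s1[[b]]$increments_deg, rater2 = s2[[b]]$increments_deg)
  })
  names(out) <- names(s1)
  out
}

#' Per-segment ICC summary
#'
#' Averages per-recording ICC values within each segment and flags adequacy
#' (ICC above 0.60) per value and per segment mean; the layout mirrors a
#' segment x recording reliability table with a mean column. Means are
#' rounded to 3 decimals for display.
#'
#' @param reports Data frame with columns `segment_label`, `recording_id`,
#'   `icc_value` (one row per segment/recording ICC).
#' @param adequacy_threshold Adequacy cut-off (default 0.60).
#' @return Object of class `icc_summary`: list with `table` (data frame:
#'   segment_label, n, mean_icc, adequate) and `reports` (input with
#'   per-value `adequate` flags).
#' @export
segment_icc_summary <- function(reports, adequacy_threshold = 0.60) {
  df <- as.data.frame(reports)
  if (!nrow(df)) stop_validation("reports is empty", "reports")
  for (nm in c("segment_label", "icc_value")) {
    if (!nm %in% names(df)) {
      stop_validation(sprintf("reports need a '%s' column", nm), nm)
    }
  }
  if (anyNA(df$icc_value)) {
    stop_validation("icc_value must not contain missing values", "icc_value")
  }
  segs <- unique(df$segment_label)
  tab <- do.call(rbind, lapply(segs, function(s) {
    v <- df$icc_value[df$segment_label == s]
    if (!length(v)) stop_validation(sprintf("empty segment group '%s'", s),
                                    "segment_label")
    data.frame(segment_label = s, n = length(v),
               mean_icc = round(mean(v), 3L),
               adequate = mean(v) > adequacy_threshold,
               stringsAsFactors = FALSE)
  }))
  df$adequate <- df$icc_value > adequacy_threshold
  structure(list(table = tab, reports = df,
                 adequacy_threshold = adequacy_threshold),
            class = "icc_summary")
}

#' @export
print.icc_summary <- function(x, ...) {
  cat(sprintf("Per-segment ICC means (adequate when > %.2f):\n",
              x$adequacy_threshold))
  tab <- x$table
  tab$mean_icc <- sprintf("%.3f%s", tab$mean_icc,
                          ifelse(tab$adequate, "", " (inadequate)"))
  print(tab[, c("segment_label", "n", "mean_icc")], row.names = FALSE)
  invisible(x)
}

#' Reference two-analyst reliability table
#'
#' Loads the bundled per-(segment, recording) ICC values from a two-analyst
#' re-evaluation of five lumbar cine recordings, in the layout consumed by
#' [segment_icc_summary()].
#'
#' @return Data frame with columns `segment_label`, `recording_id`,
#'   `icc_value`.
#' @export
reference_segment_icc <- function() {
  path <- system.file("extdata", "segment_icc_reference.csv",
                      package = "lumbartrack", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
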