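# Plain-text / standard-format interchange between pipeline stages:
# frames as multi-page TIFF or numbered PNG, template polygons as JSON
# (0-based pixel coordinates, origin top-left), poses and ground truth as CSV.

#' Template polygon for one vertebra
#'
#' A user- (or simulator-) supplied polygon outlining one vertebra on the
#' median frame of a recording; the tracker follows the bony structure
#' inside it through all frames.
#'
#' @param vertebra_label Label such as `"L3"`.
#' @param polygon Numeric n x 2 matrix of (x, y) pixel vertices (0-based,
#'   origin top-left); must be simple with at least 3 vertices and
#'   non-zero area.
#' @param reference_frame_index 1-based index of the frame the polygon was
#'   drawn on (the median frame by convention).
#' @return An object of class `template_area`.
#' @export
template_area <- function(vertebra_label, polygon, reference_frame_index) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L) {
    stop_validation("polygon must be an n x 2 matrix with n >= 3", "polygon")
  }
  if (!all(is.finite(polygon))) {
    stop_validation("polygon vertices must be finite", "polygon")
  }
  if (abs(polygon_area(polygon)) <= 0) {
    stop_validation("polygon must have non-zero area", "polygon")
  }
  if (!polygon_is_simple(polygon)) {
    stop_validation("polygon must be simple (non-self-intersecting)", "polygon")
  }
  if (length(reference_frame_index) != 1L || reference_frame_index < 1) {
    stop_validation("reference_frame_index must be a single index >= 1",
                    "reference_frame_index")
  }
  dimnames(polygon) <- list(NULL, c("x", "y"))
  structure(
    list(vertebra_label = as.character(vertebra_label),
         polygon = polygon,
         reference_frame_index = as.integer(reference_frame_index)),
    class = "template_area"
  )
}

#' Write and read frame stacks
#'
#' Frames are grayscale matrices with values in `[0, 1]`. `format = "tiff"`
#' writes one multi-page TIFF; `format = "png"` writes numbered
#' `frame_0001.png` files into a directory.
#'
#' @param frames List of numeric matrices (or a `phantom_stack`).
#' @param path Output file (TIFF) or directory (PNG).
#' @param format `"tiff"` or `"png"`.
#' @return `path`, invisibly (`write_frames`); a list of matrices
#'   (`read_frames`).
#' @export
write_frames <- function(frames, path, format = c("tiff", "png")) {
  format <- match.arg(format)
  if (inherits(frames, "phantom_stack")) frames <- frames$frames
  if (!length(frames)) stop_validation("no frames to write", "frames")
  if (format == "tiff") {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    ok <- try(tiff::writeTIFF(frames, path, bits.per.sample = 16L), silent = TRUE)
    if (inherits(ok, "try-error")) stop_io(sprintf("cannot write TIFF '%s'", path))
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(frames)) {
      f <- file.path(path, sprintf("frame_%04d.png", i))
      ok <- try(png::writePNG(frames[[i]], f), silent = TRUE)
      if (inherits(ok, "try-error")) stop_io(sprintf("cannot write PNG '%s'", f))
    }
  }
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop_io(sprintf("no PNG frames found in '%s'", path))
    lapply(files, function(f) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) img <- img[, , 1L]
      img
    })
  } else if (file.exists(path)) {
    frames <- tiff::readTIFF(path, all = TRUE)
    lapply(frames, function(img) if (length(dim(img)) == 3L) img[, , 1L] else img)
  } else {
    stop_io(sprintf("frame stack '%s' not found", path))
  }
}

#' Write and read template polygons as JSON
#'
#' The JSON uses 0-based pixel coordinates (origin top-left) and 0-based
#' frame indices; the R objects use 1-based frame indices.
#'
#' @param templates List of [template_area()] (or a `phantom_stack`).
#' @param path JSON file path.
#' @return `path`, invisibly; `read_templates_json` returns a list of
#'   [template_area()].
#' @export
write_templates_json <- function(templates, path) {
  if (inherits(templates, "phantom_stack")) templates <- templates$templates
  payload <- lapply(templates, function(tp) {
    list(vertebra_label = tp$vertebra_label,
         frame_index = tp$reference_frame_index - 1L,
         polygon = lapply(seq_len(nrow(tp$polygon)),
                          function(i) as.numeric(tp$polygon[i, ])))
  })
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_templates_json
#' @export
read_templates_json <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("template file '%s' not found", path))
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(el) {
    poly <- do.call(rbind, lapply(el$polygon, unlist))
    template_area(el$vertebra_label, poly, el$frame_index + 1L)
  })
}

#' Write and read pose tables
#'
#' Pose tables hold one row per (frame, vertebra): the rigid 2-D pose
#' relative to the reference frame plus the tracker's match score and
#' validity flag.
#'
#' @param poses Data frame with columns `frame_index`, `vertebra_label`,
#'   `rotation_deg`, `tx_px`, `ty_px`, `match_score`, `valid`.
#' @param path CSV file path.
#' @return `path`, invisibly; `read_poses_csv` returns the data frame.
#' @export
write_poses_csv <- function(poses, path) {
  need <- c("frame_index", "vertebra_label", "rotation_deg", "tx_px", "ty_px",
            "match_score", "valid")
  if (!all(need %in% names(poses))) {
    stop_validation(sprintf("poses must have columns: %s",
                            paste(need, collapse = ", ")), "poses")
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(poses[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_poses_csv
#' @export
read_poses_csv <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("pose file '%s' not found", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write ground-truth kinematics as CSV
#'
#' One row per (frame, vertebra): absolute sagittal angle and in-plane
#' translation of the rendered phantom (zero translation when no stack is
#' supplied).
#'
#' @param recording A [generate_kinematics()] result.
#' @param path CSV file path.
#' @param stack Optional [render_frames()] result supplying translations.
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(recording, path, stack = NULL) {
  truth <- if (!is.null(stack)) {
    stack$truth
  } else {
    n <- nrow(recording$angles)
    data.frame(
      frame_index = rep(seq_len(n), times = ncol(recording$angles)),
      vertebra_label = rep(recording$vertebra_labels, each = n),
      angle_deg = as.vector(recording$angles),
      tx_px = 0, ty_px = 0, stringsAsFactors = FALSE)
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
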