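# Internal helpers: conditions, seeded evaluation, 2-D geometry.

stop_validation <- function(msg, field = NULL, call. = FALSE) {
  if (!is.null(field)) msg <- sprintf("%s [field: %s]", msg, field)
  cond <- structure(
    class = c("lumbartrack_validation_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL, field = field)
  )
  stop(cond)
}

stop_io <- function(msg) {
  cond <- structure(
    class = c("lumbartrack_io_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cond)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded to `seed`, restoring
#' the caller's RNG state afterwards so library code does not perturb user
#' simulations.
#'
#' @param seed Single integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_validation("seed must be a single non-missing number", "seed")
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Rotation matrix, angle in degrees, applied to (x, y) image coordinates
# (0-based, origin top-left). Positive angles rotate counter-clockwise in
# the (x, y) basis used throughout.
rot2 <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

# Apply rigid pose (rotation about `center`, then translation) to an n x 2
# matrix of points.
apply_pose <- function(pts, theta_deg, tx, ty, center) {
  R <- rot2(theta_deg)
  sw <- sweep(pts, 2L, center)
  out <- sw %*% t(R)
  sweep(out, 2L, c(center[1] + tx, center[2] + ty), FUN = "+")
}

# Signed polygon area (shoelace); vertices as n x 2 matrix.
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1L)
  a <- polygon_area(poly)
  if (abs(a) < .Machine$double.eps) return(colMeans(poly))
  cr <- x * y[j] - x[j] * y
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# Simplicity check: no two non-adjacent edges intersect.
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  idx <- function(i) ((i - 1L) %% n) + 1L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L || (i == 1L && j == n)) next
      if (segments_intersect(poly[i, ], poly[idx(i + 1L), ],
                             poly[j, ], poly[idx(j + 1L), ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Vectorized even-odd point-in-polygon test; px, py numeric vectors,
# poly an n x 2 vertex matrix. Points exactly on an edge may fall either
# side; callers treat the polygon as a region mask, not a measure.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Bilinear sampling of matrix `img` at 0-based continuous coordinates
# (x = column, y = row). Coordinates are clamped to the image domain.
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x0 <- pmin(x0, w - 2); y0 <- pmin(y0, h - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + 1L + x0 * h          # column-major linear indices
  v00 <- img[i00]
  v10 <- img[i00 + h]
  v01 <- img[i00 + 1L]
  v11 <- img[i00 + h + 1L]
  (v00 * (1 - fx) + v10 * fx) * (1 - fy) + (v01 * (1 - fx) + v11 * fx) * fy
}

# 2x block-mean downsampling (odd trailing row/col dropped).
downsample2 <- function(img) {
  h <- 2L * (nrow(img) %/% 2L)
  w <- 2L * (ncol(img) %/% 2L)
  img <- img[seq_len(h), seq_len(w), drop = FALSE]
  (img[seq(1L, h, 2L), seq(1L, w, 2L)] + img[seq(2L, h, 2L), seq(1L, w, 2L)] +
     img[seq(1L, h, 2L), seq(2L, w, 2L)] + img[seq(2L, h, 2L), seq(2L, w, 2L)]) / 4
}

`%||%` <- function(a, b) if (is.null(a)) b else a
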