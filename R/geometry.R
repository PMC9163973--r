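# Low-level vector/geometry helpers shared across modules. All coordinates are
# millimetres in the anatomical frame: +x medial, +y anterior, +z proximal
# (right-knee convention).

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < .Machine$double.eps) abort("cannot normalise a zero-length vector", class = "tibtunnel_error_degenerate")
  v / n
}

row_norms <- function(m) sqrt(rowSums(m^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Distances from points to a 3D segment
#'
#' Computes the Euclidean distance from each row of `pts` to the segment
#' joining `a` and `b` (closest-point distance, with the parameter clamped to
#' the segment).
#'
#' @param pts numeric matrix (n x 3) of query points.
#' @param a,b numeric length-3 endpoints of the segment.
#' @return numeric vector of n distances (mm).
#' @export
point_segment_distance <- function(pts, a, b) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < .Machine$double.eps) return(sqrt(rowSums(sweep(pts, 2, a)^2)))
  d <- sweep(pts, 2, a)
  t <- pmin(1, pmax(0, (d %*% ab) / len2))
  closest <- outer(as.vector(t), ab)
  sqrt(rowSums((d - closest)^2))
}

#' Rotation matrix from axis and angle
#'
#' @param axis any nonzero 3-vector.
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  u <- unit_vec(axis)
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c_ + ux^2 * (1 - c_),      ux * uy * (1 - c_) - uz * s_, ux * uz * (1 - c_) + uy * s_,
    uy * ux * (1 - c_) + uz * s_, c_ + uy^2 * (1 - c_),      uy * uz * (1 - c_) - ux * s_,
    uz * ux * (1 - c_) - uy * s_, uz * uy * (1 - c_) + ux * s_, c_ + uz^2 * (1 - c_)
  ), nrow = 3, byrow = TRUE)
}

#' Apply a rigid motion to a point matrix
#'
#' Maps each row p to `R p + t`.
#'
#' @param pts n x 3 matrix.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector.
#' @return transformed n x 3 matrix.
#' @export
apply_rigid <- function(pts, rotation = diag(3), translation = c(0, 0, 0)) {
  sweep(matrix(as.numeric(pts), ncol = 3) %*% t(rotation), 2, -translation)
}

#' Shoelace signed area of a closed 2D polygon
#'
#' @param xy vertex matrix (first vertex not repeated); positive area means
#'   counterclockwise orientation.
#' @return signed area.
#' @export
polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

# Simple-polygon test by segment intersection scan; adequate for the modest
# vertex counts produced by slicing.
polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(FALSE)
  p1 <- xy
  p2 <- xy[c(2:n, 1), , drop = FALSE]
  segs_intersect <- function(i, j) {
    d1 <- p2[i, ] - p1[i, ]; d2 <- p2[j, ] - p1[j, ]
    denom <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(denom) < 1e-12) return(FALSE)
    dp <- p1[j, ] - p1[i, ]
    t <- (dp[1] * d2[2] - dp[2] * d2[1]) / denom
    u <- (dp[1] * d1[2] - dp[2] * d1[1]) / denom
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next
      if (segs_intersect(i, j)) return(FALSE)
    }
  }
  TRUE
}

# Linear interpolation of an ordered polyline (n x k matrix) at arc-length
# fractions `s` in [0, 1].
polyline_interp <- function(pts, s) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  target <- pmin(pmax(s, 0), 1) * total
  out <- matrix(NA_real_, length(target), ncol(pts))
  for (i in seq_along(target)) {
    j <- findInterval(target[i], cum, rightmost.closed = TRUE)
    j <- min(max(j, 1), nrow(pts) - 1)
    w <- if (seg[j] > 0) (target[i] - cum[j]) / seg[j] else 0
    out[i, ] <- (1 - w) * pts[j, ] + w * pts[j + 1, ]
  }
  out
}

#' Minimum distance from points to an ordered polyline
#'
#' @param pts query points (n x k matrix, k = 2 or 3).
#' @param line polyline vertex matrix (m x k).
#' @return numeric vector of n distances.
#' @export
point_polyline_distance <- function(pts, line) {
  pts <- matrix(as.numeric(pts), ncol = ncol(line))
  d <- rep(Inf, nrow(pts))
  for (j in seq_len(nrow(line) - 1)) {
    a <- line[j, ]; b <- line[j + 1, ]
    if (ncol(line) == 3) {
      dj <- point_segment_distance(pts, a, b)
    } else {
      ab <- b - a
      len2 <- sum(ab^2)
      dp <- sweep(pts, 2, a)
      t <- if (len2 > 0) pmin(1, pmax(0, (dp %*% ab) / len2)) else matrix(0, nrow(pts), 1)
      dj <- sqrt(rowSums((dp - outer(as.vector(t), ab))^2))
    }
    d <- pmin(d, dj)
  }
  d
}
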