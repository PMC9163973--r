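#' Axial cross-section of a mesh
#'
#' Intersects the mesh with the plane `z = z_level` and returns the largest
#' closed contour as a counterclockwise 2D polygon (x medial, y anterior,
#' viewed from proximal).
#'
#' @param mesh a [triangle_mesh()].
#' @param z_level axial level (mm).
#' @return an object of class `cross_section_outline`: list with `z_level` and
#'   `polygon` (k x 2 matrix, closed, first vertex not repeated).
#' @export
slice_cross_section <- function(mesh, z_level) {
  vz <- mesh$vertices[, 3]
  if (z_level <= min(vz) || z_level >= max(vz)) {
    abort(sprintf("slice plane z = %.3f does not intersect the mesh (z range %.3f .. %.3f)",
                  z_level, min(vz), max(vz)),
          class = "tibtunnel_error_empty_slice")
  }
  # nudge off exact vertex hits so every crossing is through an edge interior
  for (try in 1:6) {
    if (min(abs(vz - z_level)) > 1e-9) break
    z_level <- z_level + 1e-7
  }
  f <- mesh$faces
  dz <- matrix(vz[f] - z_level, ncol = 3)
  crossing <- which(matrixStats_rowMins(dz) < 0 & matrixStats_rowMaxs(dz) > 0)
  if (!length(crossing)) {
    abort("slice plane misses the mesh interior", class = "tibtunnel_error_empty_slice")
  }

  # for each crossing face, the two edges that change sign
  fi <- f[crossing, , drop = FALSE]
  di <- dz[crossing, , drop = FALSE]
  epairs <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  seg_a_key <- seg_b_key <- numeric(length(crossing))
  seg_a_pt <- seg_b_pt <- matrix(NA_real_, length(crossing), 2)
  for (row in seq_along(crossing)) {
    found <- 0L
    for (e in epairs) {
      da <- di[row, e[1]]; db <- di[row, e[2]]
      if ((da < 0) != (db < 0)) {
        ia <- fi[row, e[1]]; ib <- fi[row, e[2]]
        t <- da / (da - db)
        p <- (1 - t) * mesh$vertices[ia, 1:2] + t * mesh$vertices[ib, 1:2]
        key <- edge_keys(ia, ib)
        found <- found + 1L
        if (found == 1L) { seg_a_key[row] <- key; seg_a_pt[row, ] <- p }
        else { seg_b_key[row] <- key; seg_b_pt[row, ] <- p }
      }
    }
  }

  # chain face segments into closed loops via shared mesh-edge keys
  keys <- unique(c(seg_a_key, seg_b_key))
  a_id <- match(seg_a_key, keys); b_id <- match(seg_b_key, keys)
  pts <- matrix(NA_real_, length(keys), 2)
  pts[a_id, ] <- seg_a_pt; pts[b_id, ] <- seg_b_pt
  # adjacency: each edge key connects to up to two partner keys
  nb1 <- nb2 <- integer(length(keys))
  add_link <- function(from, to) {
    for (k in seq_along(from)) {
      i <- from[k]
      if (nb1[i] == 0L) nb1[i] <<- to[k] else nb2[i] <<- to[k]
    }
  }
  add_link(a_id, b_id); add_link(b_id, a_id)
  if (any(nb2 == 0L)) {
    abort("open intersection contour: mesh is not closed at this level",
          class = "tibtunnel_error_mesh")
  }
  visited <- logical(length(keys))
  loops <- list()
  for (start in seq_along(keys)) {
    if (visited[start]) next
    loop <- integer(0)
    cur <- start; prev <- 0L
    repeat {
      visited[cur] <- TRUE
      loop <- c(loop, cur)
      nxt <- if (nb1[cur] != prev) nb1[cur] else nb2[cur]
      prev <- cur; cur <- nxt
      if (cur == start) break
    }
    loops[[length(loops) + 1]] <- loop
  }
  areas <- vapply(loops, function(l) abs(polygon_signed_area(pts[l, , drop = FALSE])), 1)
  poly <- pts[loops[[which.max(areas)]], , drop = FALSE]
  if (polygon_signed_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  structure(list(z_level = z_level, polygon = poly), class = "cross_section_outline")
}

# rowMins/rowMaxs without extra dependencies
matrixStats_rowMins <- function(m) do.call(pmin, as.data.frame(m))
matrixStats_rowMaxs <- function(m) do.call(pmax, as.data.frame(m))

#' @export
print.cross_section_outline <- function(x, ...) {
  cat(sprintf("<cross_section_outline> z = %.2f mm, %d vertices, area %.1f mm^2\n",
              x$z_level, nrow(x$polygon), abs(polygon_signed_area(x$polygon))))
  invisible(x)
}
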