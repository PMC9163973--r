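#' Medial tibial plateau reference plane
#'
#' Container for plane M: the plane of the medial tibial plateau through the
#' landmarks E (anterior peak of the medial rim), F (most medial rim point)
#' and G (posterior peak), with the best-fit circle of the rim.
#'
#' @param E,F_pt,G length-3 landmark coordinates (mm).
#' @param normal unit normal, oriented into the proximal (+z) hemisphere.
#' @param circle_center,circle_radius best-fit circle of the rim (mm).
#' @return object of class `plateau_plane`.
#' @export
plateau_plane <- function(E, F_pt, G, normal, circle_center = NULL,
                          circle_radius = NA_real_) {
  n <- unit_vec(normal)
  if (n[3] <= 0) n <- -n
  obj <- structure(list(E = E, F = F_pt, G = G, normal = n,
                        circle_center = circle_center,
                        circle_radius = circle_radius),
                   class = "plateau_plane")
  if (abs(sum(n * (F_pt - E))) > 1e-6 * max(1, vec_norm(F_pt - E)) ||
      abs(sum(n * (G - E))) > 1e-6 * max(1, vec_norm(G - E))) {
    abort("normal is not perpendicular to the E/F/G plane", class = "tibtunnel_error_degenerate")
  }
  obj
}

#' @export
print.plateau_plane <- function(x, ...) {
  cat("<plateau_plane>\n")
  cat(sprintf("  normal  (%.4f, %.4f, %.4f)\n", x$normal[1], x$normal[2], x$normal[3]))
  cat(sprintf("  E (%.1f, %.1f, %.1f)  F (%.1f, %.1f, %.1f)  G (%.1f, %.1f, %.1f)\n",
              x$E[1], x$E[2], x$E[3], x$F[1], x$F[2], x$F[3], x$G[1], x$G[2], x$G[3]))
  if (!is.null(x$circle_center)) {
    cat(sprintf("  rim circle radius %.2f mm\n", x$circle_radius))
  }
  invisible(x)
}

# signed distance of points (n x 3) above plane M
plane_signed_distance <- function(pts, plane) {
  as.vector(sweep(matrix(as.numeric(pts), ncol = 3), 2, plane$E) %*% plane$normal)
}

#' Extract the medial plateau rim from a mesh
#'
#' The rim is the boundary polyline of the connected upward-facing surface
#' region (face normals within `up_cone_deg` of the `up` direction) restricted
#' to the medial half (x > 0 in the anatomical frame).
#'
#' @param mesh a [triangle_mesh()].
#' @param up_cone_deg half-angle of the upward normal cone (degrees).
#' @param up reference "proximal" direction (default +z).
#' @param medial reference "medial" direction (default +x).
#' @return ordered 3D polyline (matrix) of the medial rim.
#' @export
extract_medial_rim <- function(mesh, up_cone_deg = 45, up = c(0, 0, 1),
                               medial = c(1, 0, 0)) {
  up <- unit_vec(up); medial <- unit_vec(medial)
  fn <- mesh_face_normals(mesh)
  upward <- which(as.vector(fn %*% up) > cos(deg2rad(up_cone_deg)))
  if (!length(upward)) {
    abort("no upward-facing surface region found", class = "tibtunnel_error_mesh")
  }
  # largest connected component of the upward set (face adjacency via edges)
  f <- mesh$faces[upward, , drop = FALSE]
  ekey <- cbind(edge_keys(f[, 1], f[, 2]), edge_keys(f[, 2], f[, 3]), edge_keys(f[, 3], f[, 1]))
  comp <- rep(0L, length(upward))
  cid <- 0L
  key_to_faces <- split(rep(seq_along(upward), 3), as.vector(ekey))
  for (s in seq_along(upward)) {
    if (comp[s]) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      fc <- queue[[1]]; queue <- queue[-1]
      for (k in 1:3) {
        nbrs <- key_to_faces[[as.character(ekey[fc, k])]]
        nbrs <- nbrs[comp[nbrs] == 0L]
        comp[nbrs] <- cid
        queue <- c(queue, nbrs)
      }
    }
  }
  # keep the component with the largest surface area (the plateau), not the
  # largest face count: narrow upward-facing ledges elsewhere can be finely
  # meshed
  areas_all <- mesh_face_areas(mesh)[upward]
  comp_area <- vapply(seq_len(cid), function(ci) sum(areas_all[comp == ci]), 1)
  main <- which(comp == which.max(comp_area))
  f <- f[main, , drop = FALSE]
  # boundary edges: used once within the region
  i <- c(f[, 1], f[, 2], f[, 3]); j <- c(f[, 2], f[, 3], f[, 1])
  und <- edge_keys(i, j)
  once <- und %in% names(which(table(und) == 1L))
  bi <- i[once]; bj <- j[once]
  if (!length(bi)) abort("upward-facing region has no boundary", class = "tibtunnel_error_mesh")
  # chain boundary edges into loops and keep the longest (the outer rim)
  nxt <- integer(max(c(bi, bj)))
  nxt[bi] <- bj
  remaining <- rep(TRUE, length(bi))
  names(remaining) <- as.character(bi)
  loops <- list()
  for (s in bi) {
    if (!remaining[[as.character(s)]]) next
    loop <- integer(0)
    cur <- s
    repeat {
      loop <- c(loop, cur)
      remaining[[as.character(cur)]] <- FALSE
      cur <- nxt[cur]
      if (cur == s || length(loop) > length(bi) + 1) break
    }
    loops[[length(loops) + 1]] <- loop
  }
  loop <- loops[[which.max(lengths(loops))]]
  ring <- mesh$vertices[loop, , drop = FALSE]
  med <- which(as.vector(ring %*% medial) > 0)
  if (length(med) < 4) abort("medial rim degenerate (too few points with x > 0)",
                             class = "tibtunnel_error_mesh")
  breaks <- which(diff(med) > 1)
  if (length(breaks)) med <- c(med[(breaks[1] + 1):length(med)], med[seq_len(breaks[1])])
  ring[med, , drop = FALSE]
}

#' Least-squares circle fit in 2D
#'
#' Algebraic (Kasa) fit followed by Gauss-Newton refinement of the geometric
#' objective `sum((|p - c| - r)^2)`.
#'
#' @param xy n x 2 matrix.
#' @param max_iter,tol refinement control.
#' @return list with `center` (length 2), `radius`, `rss`.
#' @export
fit_circle_2d <- function(xy, max_iter = 50, tol = 1e-12) {
  x <- xy[, 1]; y <- xy[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) {
    abort("degenerate circle fit (collinear or insufficient points)",
          class = "tibtunnel_error_degenerate", parent = e)
  })
  cx <- sol[1]; cy <- sol[2]
  r <- sqrt(sol[3] + cx^2 + cy^2)
  for (it in seq_len(max_iter)) {
    dx <- x - cx; dy <- y - cy
    di <- sqrt(dx^2 + dy^2)
    if (any(di < 1e-12)) break
    res <- di - r
    J <- cbind(-dx / di, -dy / di, -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 3))
    cx <- cx + step[1]; cy <- cy + step[2]; r <- r + step[3]
    if (sum(step^2) < tol^2) break
  }
  dx <- x - cx; dy <- y - cy
  list(center = c(cx, cy), radius = r, rss = sum((sqrt(dx^2 + dy^2) - r)^2))
}

#' Fit plane M from the medial plateau rim
#'
#' A least-squares plane gives the working orientation; the rim is projected
#' into it and a best-fit circle computed. The landmarks are rim vertices:
#' E = maximal-elevation point of the anterior half (anterior of the circle
#' centre), G = maximal elevation of the posterior half, F = most medial
#' point. Plane M is the plane through E, F and G with proximally oriented
#' normal.
#'
#' @param rim ordered 3D polyline (>= 8 points) of the medial plateau rim.
#' @param up,anterior,medial frame directions used to orient the construction.
#' @return a [plateau_plane()] object.
#' @export
fit_plane_M <- function(rim, up = c(0, 0, 1), anterior = c(0, 1, 0),
                        medial = c(1, 0, 0)) {
  rim <- matrix(as.numeric(rim), ncol = 3)
  if (nrow(rim) < 8) abort("rim needs at least 8 points", class = "tibtunnel_error_degenerate")
  ctr <- colMeans(rim)
  sv <- svd(sweep(rim, 2, ctr))
  w_n <- sv$v[, 3]                      # working plane normal
  if (sum(w_n * up) < 0) w_n <- -w_n
  e1 <- unit_vec(sv$v[, 1]); e2 <- unit_vec(sv$v[, 2])
  proj <- cbind(sweep(rim, 2, ctr) %*% e1, sweep(rim, 2, ctr) %*% e2)
  circ <- fit_circle_2d(proj)
  center3 <- ctr + circ$center[1] * e1 + circ$center[2] * e2

  elev <- as.vector(rim %*% unit_vec(up))
  ant_proj <- as.vector(sweep(rim, 2, center3) %*% unit_vec(anterior))
  ant <- ant_proj > 0
  if (!any(ant) || all(ant)) {
    abort("rim does not straddle the circle centre anterior-posteriorly",
          class = "tibtunnel_error_degenerate")
  }
  # elevation maxima; a flat rim ties everywhere, in which case the anterior
  # peak is the most anterior point and the posterior peak the most posterior
  iE <- which(ant)[order(-round(elev[ant], 9), -ant_proj[ant])[1]]
  iG <- which(!ant)[order(-round(elev[!ant], 9), ant_proj[!ant])[1]]
  iF <- which.max(as.vector(rim %*% unit_vec(medial)))
  E <- rim[iE, ]; G <- rim[iG, ]; F_pt <- rim[iF, ]
  n <- cross3(F_pt - E, G - E)
  if (vec_norm(n) < 1e-9 * max(vec_norm(F_pt - E), vec_norm(G - E))) {
    abort("landmarks E, F, G are collinear", class = "tibtunnel_error_degenerate")
  }
  plateau_plane(E, F_pt, G, n, circle_center = center3, circle_radius = circ$radius)
}

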