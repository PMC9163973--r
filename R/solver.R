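#' Tunnel specification
#'
#' @param exit_B 3D exit point (the PCL attachment centre).
#' @param track an [entry_track()] for the approach.
#' @param radius tunnel radius (mm); the classical simulation uses 5 mm.
#' @param search_z length-2 z interval searched on the track (default: the
#'   full track extent).
#' @param clearance_tol convergence band for the tangency clearance (mm).
#' @return object of class `tunnel_spec`.
#' @export
tunnel_spec <- function(exit_B, track, radius = 5,
                        search_z = range(track$pts[, 3]), clearance_tol = 0.05) {
  if (radius <= 0) abort("radius must be > 0", class = "tibtunnel_error_params")
  if (diff(range(search_z)) <= 0) abort("search_z must be a nonempty interval",
                                        class = "tibtunnel_error_params")
  tz <- range(track$pts[, 3])
  if (min(search_z) < tz[1] - 1e-9 || max(search_z) > tz[2] + 1e-9) {
    abort("search_z must lie within the track extent", class = "tibtunnel_error_params")
  }
  structure(list(exit_B = as.numeric(exit_B), track = track, radius = radius,
                 search_z = sort(as.numeric(search_z)), clearance_tol = clearance_tol),
            class = "tunnel_spec")
}

# deterministic barycentric refinement pattern: all (i, j, k) / n with
# i + j + k = n; includes corners and edges so sharp boundary edges are sampled
bary_grid <- function(n) {
  i <- rep(0:n, times = n + 1)
  j <- rep(0:n, each = n + 1)
  keep <- i + j <= n
  cbind(i[keep], j[keep], n - i[keep] - j[keep]) / n
}

#' Sample the posterior tibial cortex
#'
#' Returns deterministic surface sample points on posterior-facing cortex
#' (face normal within `cone_deg` of the posterior direction) below plane M,
#' excluding a ball of `exclusion_radius` around the tunnel exit aperture.
#' Each face receives a barycentric refinement grid sized so the sample count
#' meets the area density, which keeps the sampling exactly equivariant under
#' rigid motion and isotropic scaling.
#'
#' @param mesh a [triangle_mesh()].
#' @param exit_B tunnel exit point (mm).
#' @param exclusion_radius radius of the excluded ball around `exit_B` (mm);
#'   default tunnel radius + 1.
#' @param plane_M a [plateau_plane()]; only surface below the plane is kept
#'   (`NULL` keeps all heights).
#' @param posterior direction of the posterior normal cone (default -y).
#' @param cone_deg half-angle of the posterior cone (degrees).
#' @param density minimal sample density (points per mm^2).
#' @param radius tunnel radius used for the default exclusion (mm).
#' @return n x 3 matrix of sample points.
#' @export
posterior_cortex_samples <- function(mesh, exit_B, exclusion_radius = radius + 1,
                                     plane_M = NULL, posterior = c(0, -1, 0),
                                     cone_deg = 60, density = 4, radius = 5) {
  posterior <- unit_vec(posterior)
  fn <- mesh_face_normals(mesh)
  keep <- as.vector(fn %*% posterior) > cos(deg2rad(cone_deg))
  if (!is.null(plane_M)) {
    keep <- keep & plane_signed_distance(mesh_face_centroids(mesh), plane_M) < 0
  }
  if (!any(keep)) {
    abort("no posterior-facing cortex faces found", class = "tibtunnel_error_mesh")
  }
  faces <- which(keep)
  areas <- mesh_face_areas(mesh)[faces]
  v1 <- face_corner(mesh, 1)[faces, , drop = FALSE]
  v2 <- face_corner(mesh, 2)[faces, , drop = FALSE]
  v3 <- face_corner(mesh, 3)[faces, , drop = FALSE]
  # round before ceiling so the pattern is stable under the floating-point
  # noise of an exactly scaled mesh (area * s^2 times density / s^2)
  target <- pmax(3, ceiling(round(areas * density, 6)))
  # grid level n gives (n+1)(n+2)/2 points
  lev <- ceiling((sqrt(8 * target + 1) - 3) / 2)
  out <- vector("list", length(unique(lev)))
  ulev <- sort(unique(lev))
  for (li in seq_along(ulev)) {
    n <- ulev[li]
    g <- bary_grid(n)
    rows <- which(lev == n)
    pts <- matrix(NA_real_, length(rows) * nrow(g), 3)
    for (c_ in 1:3) {
      pts[, c_] <- as.vector(outer(g[, 1], v1[rows, c_]) + outer(g[, 2], v2[rows, c_]) +
                               outer(g[, 3], v3[rows, c_]))
    }
    out[[li]] <- pts
  }
  pts <- do.call(rbind, out)
  pts <- pts[!duplicated(round(pts, 9)), , drop = FALSE]
  d_b <- sqrt(rowSums(sweep(pts, 2, exit_B)^2))
  pts <- pts[d_b > exclusion_radius, , drop = FALSE]
  if (!nrow(pts)) {
    warn("exclusion radius removed every posterior cortex sample")
  }
  pts
}

#' Clearance of a candidate tunnel against the posterior cortex
#'
#' Minimum over the cortex samples of (distance to the tunnel centreline
#' segment A-B) minus the tunnel radius. Negative values mean the cylinder
#' breaches the cortex.
#'
#' @param entry_A entry point (mm).
#' @param spec a [tunnel_spec()].
#' @param samples matrix from [posterior_cortex_samples()].
#' @return clearance in mm.
#' @export
clearance <- function(entry_A, spec, samples) {
  if (is.null(samples) || nrow(samples) == 0) {
    abort("empty posterior cortex sample set", class = "tibtunnel_error_params")
  }
  if (sqrt(sum((entry_A - spec$exit_B)^2)) < 1e-9) {
    abort("entry and exit coincide", class = "tibtunnel_error_degenerate")
  }
  min(point_segment_distance(samples, entry_A, spec$exit_B)) - spec$radius
}

#' Solve the maximally inclined safe tunnel for one approach
#'
#' Finds the most distal entry point on the track whose 5-mm cylinder to the
#' fixed exit still clears the posterior cortex: a coarse proximal-to-distal
#' scan locates the feasibility boundary, bisection refines the entry height
#' to 0.01 mm, and the returned tunnel is tangent to the cortex within the
#' clearance tolerance. Because entry points lower on the track give steeper
#' tunnels, this entry maximises the angle against the tibial plateau (the
#' permissive safe angle). A non-monotone clearance profile (pathological
#' shapes) is detected in the scan, in which case the solver falls back to an
#' exhaustive fine grid and flags the result.
#'
#' @param mesh a [triangle_mesh()] (used when `samples` not supplied).
#' @param spec a [tunnel_spec()].
#' @param plane_M a [plateau_plane()].
#' @param samples optional precomputed [posterior_cortex_samples()].
#' @param scan_step coarse scan step along the track (mm of arc length).
#' @param z_tol bisection tolerance on the entry position (mm of arc length;
#'   at least as tight on the entry height, since the track is z-monotone).
#' @param exclusion_radius forwarded to [posterior_cortex_samples()] when
#'   `samples` is not supplied; use 0 for fixtures whose exit aperture does
#'   not touch the cortex.
#' @return object of class `tunnel`: approach, `entry_A`, `exit_B`, unit
#'   `axis` (A to B), `radius`, `clearance`, `psa_deg`, flags `converged` and
#'   `monotone`, and the scan diagnostics table (`scan`).
#' @export
solve_max_angle_tunnel <- function(mesh, spec, plane_M, samples = NULL,
                                   scan_step = 2, z_tol = 0.01,
                                   exclusion_radius = spec$radius + 1) {
  if (is.null(samples)) {
    samples <- posterior_cortex_samples(mesh, spec$exit_B, radius = spec$radius,
                                        exclusion_radius = exclusion_radius,
                                        plane_M = plane_M)
  }
  # the track is searched by arc length from its proximal end, an intrinsic
  # parameter that makes the solve equivariant under rigid motion; the track
  # is z-monotone, so arc length and entry height are interchangeable
  pts <- spec$track$pts
  seg_len <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  cum_s <- c(0, cumsum(seg_len))
  z_monotone <- !is.unsorted(rev(pts[, 3]), strictly = TRUE)
  s_of_z <- function(z) {
    # in a rotated frame z is not a track parameter: search the whole track
    if (!z_monotone) return(if (z == spec$search_z[2]) 0 else cum_s[length(cum_s)])
    stats::approx(pts[, 3], cum_s, xout = z, rule = 2)$y
  }
  point_at_s <- function(s) {
    j <- findInterval(s, cum_s, rightmost.closed = TRUE)
    j <- min(max(j, 1), nrow(pts) - 1)
    w <- if (seg_len[j] > 0) (s - cum_s[j]) / seg_len[j] else 0
    (1 - w) * pts[j, ] + w * pts[j + 1, ]
  }
  cl_at <- function(s) clearance(point_at_s(s), spec, samples)
  s_hi <- s_of_z(spec$search_z[2])   # proximal end: smallest arc length
  s_lo <- s_of_z(spec$search_z[1])
  ss <- unique(c(seq(s_hi, s_lo, by = scan_step), s_lo))
  cl <- vapply(ss, cl_at, 1)
  psa_at <- function(s) {
    u <- unit_vec(spec$exit_B - point_at_s(s))
    rad2deg(asin(min(1, abs(sum(u * plane_M$normal)))))
  }
  scan <- tibble(z = vapply(ss, function(s) point_at_s(s)[3], 1),
                 arc_s = ss, clearance = cl,
                 psa_deg = vapply(ss, psa_at, 1))
  if (cl[1] < 0) {
    if (all(cl < 0)) {
      abort(sprintf("infeasible tunnel: clearance < 0 along the whole track (max %.3f mm)",
                    max(cl)),
            class = "tibtunnel_error_infeasible")
    }
    abort(sprintf(paste0("shallowest candidate is unsafe (clearance %.3f mm); ",
                         "extend search_z proximally"), cl[1]),
          class = "tibtunnel_error_infeasible")
  }
  # monotonicity guard: clearance should decrease with depth
  monotone <- all(diff(cl) <= max(0.2, 0.05 * scan_step))
  if (!monotone) {
    ss_f <- unique(c(seq(s_hi, s_lo, by = scan_step / 8), s_lo))
    cl_f <- vapply(ss_f, cl_at, 1)
    feas <- which(cl_f >= 0)
    k <- max(feas)
    s_feas <- ss_f[k]
    s_infeas <- if (k < length(ss_f)) ss_f[k + 1] else NA_real_
  } else {
    first_neg <- which(cl < 0)
    if (!length(first_neg)) {
      # whole track feasible: deepest entry, not a tangent solution
      s_feas <- ss[length(ss)]
      s_infeas <- NA_real_
    } else {
      k <- min(first_neg)
      s_feas <- ss[k - 1]
      s_infeas <- ss[k]
    }
  }
  c_feas <- cl_at(s_feas)
  if (!is.na(s_infeas)) {
    for (it in 1:80) {
      if (abs(s_feas - s_infeas) < z_tol && c_feas <= spec$clearance_tol) break
      s_mid <- (s_feas + s_infeas) / 2
      c_mid <- cl_at(s_mid)
      if (c_mid >= 0) { s_feas <- s_mid; c_feas <- c_mid } else s_infeas <- s_mid
    }
  }
  entry_A <- point_at_s(s_feas)
  axis <- unit_vec(spec$exit_B - entry_A)
  psa <- rad2deg(asin(abs(sum(axis * plane_M$normal))))
  converged <- !is.na(s_infeas) && c_feas >= 0 && c_feas <= spec$clearance_tol
  structure(list(approach = spec$track$approach, entry_A = entry_A,
                 exit_B = spec$exit_B, axis = axis, radius = spec$radius,
                 clearance = c_feas, psa_deg = psa, converged = converged,
                 monotone = monotone, scan = scan),
            class = "tunnel")
}

#' @export
print.tunnel <- function(x, ...) {
  cat(sprintf("<tunnel %s> PSA %.2f deg, clearance %.4f mm, %s%s\n",
              x$approach, x$psa_deg, x$clearance,
              if (x$converged) "converged" else "not converged (track exhausted)",
              if (x$monotone) "" else ", non-monotone scan (grid fallback)"))
  invisible(x)
}
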