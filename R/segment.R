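#' Tolerances for cortical segmentation
#'
#' @param flatness_tol maximal vertex-to-chord deviation inside a straight run
#'   (mm).
#' @param min_flat_length minimal Euclidean length of a cortical flat (mm).
#' @param min_anterior_normal minimal outward-normal y-component for a run to
#'   count as cortical flat; the default excludes the posterior arc (normals
#'   near (0, -1)) while keeping an anterolateral flat perpendicular to the
#'   posterior margin (normal y near 0).
#' @return a named list.
#' @export
segmentation_config <- function(flatness_tol = 0.25, min_flat_length = 5,
                                min_anterior_normal = -0.5) {
  list(flatness_tol = flatness_tol, min_flat_length = min_flat_length,
       min_anterior_normal = min_anterior_normal)
}

# deviation of interior points from the chord first->last of a polyline
max_chord_deviation <- function(pts) {
  n <- nrow(pts)
  if (n <= 2) return(0)
  a <- pts[1, ]; b <- pts[n, ]
  d <- b - a
  len <- sqrt(sum(d^2))
  if (len < 1e-12) return(Inf)
  inner <- pts[2:(n - 1), , drop = FALSE]
  abs((inner[, 1] - a[1]) * d[2] - (inner[, 2] - a[2]) * d[1]) / len
}

# all maximal straight runs (cyclic index ranges) of a closed polygon, grown
# forward from successive anchors and then extended backward so each recorded
# run is maximal on both ends
maximal_straight_runs <- function(poly, tol) {
  n <- nrow(poly)
  pget <- function(rng) poly[((rng - 1) %% n) + 1, , drop = FALSE]
  runs <- list()
  i <- 1L
  while (i <= n) {
    j <- i + 1L
    while (j - i + 1L < n) {
      if (max(max_chord_deviation(pget(i:(j + 1L)))) > tol) break
      j <- j + 1L
    }
    i2 <- i
    while (j - i2 + 1L < n) {
      if (max(max_chord_deviation(pget((i2 - 1L):j))) > tol) break
      i2 <- i2 - 1L
    }
    runs[[length(runs) + 1L]] <- c(i2, j)
    i <- j
  }
  runs
}

run_points <- function(poly, run) {
  n <- nrow(poly)
  idx <- ((seq(run[1], run[2]) - 1) %% n) + 1
  poly[idx, , drop = FALSE]
}

run_length_mm <- function(poly, run) {
  p <- run_points(poly, run)
  sqrt(sum((p[nrow(p), ] - p[1, ])^2))
}

# outward normal of a CCW-polygon run (right-hand side of travel direction)
run_outward_normal <- function(poly, run) {
  p <- run_points(poly, run)
  d <- unit_vec(p[nrow(p), ] - p[1, ])
  c(d[2], -d[1])
}

# total-least-squares direction of a point run (first principal component)
fit_direction <- function(pts) {
  c0 <- sweep(pts, 2, colMeans(pts))
  sv <- svd(c0)
  d <- sv$v[, 1]
  # orient along travel
  if (sum(d * (pts[nrow(pts), ] - pts[1, ])) < 0) d <- -d
  d
}

#' Construct a cortex segmentation object
#'
#' Normally produced by [segment_cortex()]; the constructor is exported so
#' idealized segmentations (e.g. an exact triangle) can be built directly.
#'
#' @param am_flat,al_flat 2x2 matrices of flat endpoints, anterior row first.
#' @param am_run,al_run polylines of polygon vertices supporting each flat
#'   (default: the endpoints themselves).
#' @param crest_pts polyline of the crest arc between the flats (default: the
#'   two anterior endpoints).
#' @param posterior_tangent list with `point` and `dir` of the posterior
#'   support line.
#' @param z_level axial level (mm), if known.
#' @return an object of class `cortex_segmentation`.
#' @export
cortex_segmentation <- function(am_flat, al_flat,
                                am_run = am_flat, al_run = al_flat,
                                crest_pts = rbind(am_flat[1, ], al_flat[1, ]),
                                posterior_tangent = NULL, z_level = NA_real_) {
  structure(list(am_flat = am_flat, al_flat = al_flat,
                 am_run = am_run, al_run = al_run, crest_pts = crest_pts,
                 am_dir = unit_vec(am_flat[2, ] - am_flat[1, ]),
                 al_dir = unit_vec(al_flat[2, ] - al_flat[1, ]),
                 posterior_tangent = posterior_tangent, z_level = z_level),
            class = "cortex_segmentation")
}

#' Segment the cortical outline of an axial cross-section
#'
#' Identifies the anteromedial and anterolateral cortical flats as the two
#' longest maximal straight runs (vertex-to-chord deviation below the flatness
#' tolerance) whose outward normals face anteriorly, the crest arc between
#' them, and the posterior tangent: the support line of the posterior extreme
#' perpendicular to the anterolateral flat direction.
#'
#' @param outline a [slice_cross_section()] result, or a bare polygon matrix.
#' @param config a [segmentation_config()].
#' @return a `cortex_segmentation` object; flats are stored with their
#'   anterior (crest-side) endpoint first.
#' @export
segment_cortex <- function(outline, config = segmentation_config()) {
  poly <- if (inherits(outline, "cross_section_outline")) outline$polygon else outline
  z_level <- if (inherits(outline, "cross_section_outline")) outline$z_level else NA_real_
  if (nrow(poly) < 3) abort("outline too small", class = "tibtunnel_error_segmentation")
  if (polygon_signed_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]

  runs <- maximal_straight_runs(poly, config$flatness_tol)
  lens <- vapply(runs, function(r) run_length_mm(poly, r), 1)
  norms <- t(vapply(runs, function(r) run_outward_normal(poly, r), numeric(2)))
  dirs <- lapply(runs, function(r) fit_direction(run_points(poly, r)))
  # exclude the near-straight pieces of the posterior arc, whose outward
  # normals point posteriorly; the AL flat can have an almost horizontal
  # normal so the cut sits well below zero
  candidate <- norms[, 2] > config$min_anterior_normal & lens >= config$min_flat_length
  cand <- which(candidate)
  cand <- cand[order(lens[cand], decreasing = TRUE)]
  flat1 <- if (length(cand)) cand[1] else NULL
  flat2 <- NULL
  for (k in cand[-1]) {
    if (is.null(flat1)) break
    ang <- rad2deg(acos(min(1, abs(sum(dirs[[flat1]] * dirs[[k]])))))
    if (ang > 15) { flat2 <- k; break }
  }
  if (is.null(flat1) || is.null(flat2)) {
    best <- if (any(candidate)) max(lens[candidate]) else 0
    abort(sprintf(paste0("cortex segmentation failed: need two anterior straight runs ",
                         ">= %.1f mm with distinct directions; longest run found was %.1f mm"),
                  config$min_flat_length, best),
          class = "tibtunnel_error_segmentation")
  }

  orient_run <- function(pts) {
    # anterior (crest-side) endpoint first
    if (pts[1, 2] < pts[nrow(pts), 2]) pts[rev(seq_len(nrow(pts))), , drop = FALSE] else pts
  }
  run1 <- orient_run(run_points(poly, runs[[flat1]]))
  run2 <- orient_run(run_points(poly, runs[[flat2]]))

  # the anteromedial cortex is oblique to the posterior margin, the
  # anterolateral cortex nearly perpendicular to it: classify by obliquity to
  # the chord joining the posterior endpoints (the triangle base); ties (a
  # mirror-symmetric outline) fall back to the medial/lateral side
  base_dir <- unit_vec(run2[nrow(run2), ] - run1[nrow(run1), ])
  obliquity <- function(run) {
    d <- fit_direction(run)
    rad2deg(acos(min(1, abs(sum(d * base_dir)))))
  }
  o1 <- obliquity(run1); o2 <- obliquity(run2)
  if (abs(o1 - o2) > 1e-6) {
    am_first <- o1 < o2        # smaller angle to the base = more oblique flat
  } else {
    am_first <- mean(run1[, 1]) > mean(run2[, 1])
  }
  am_run <- if (am_first) run1 else run2
  al_run <- if (am_first) run2 else run1
  i_am <- if (am_first) flat1 else flat2
  i_al <- if (am_first) flat2 else flat1
  am_flat <- am_run[c(1, nrow(am_run)), , drop = FALSE]
  al_flat <- al_run[c(1, nrow(al_run)), , drop = FALSE]

  # crest arc: polygon vertices between the anterior ends of the two runs.
  # CCW order runs AM (posterior->anterior), crest, AL (anterior->posterior).
  n <- nrow(poly)
  am_ant_idx <- ((runs[[i_am]][2] - 1) %% n) + 1
  al_ant_idx <- ((runs[[i_al]][1] - 1) %% n) + 1
  if (al_ant_idx >= am_ant_idx) {
    crest_idx <- seq(am_ant_idx, al_ant_idx)
  } else {
    crest_idx <- c(seq(am_ant_idx, n), seq_len(al_ant_idx))
  }
  crest_pts <- poly[crest_idx, , drop = FALSE]

  al_dir <- fit_direction(al_run)
  # posterior support line perpendicular to the AL flat direction
  n_post <- if (al_dir[2] > 0) -al_dir else al_dir   # posterior-pointing
  support <- poly[which.max(poly %*% n_post), ]
  tangent <- list(point = support, dir = c(n_post[2], -n_post[1]))

  seg <- cortex_segmentation(am_flat, al_flat, am_run, al_run, crest_pts,
                             posterior_tangent = tangent, z_level = z_level)
  seg$am_dir_fit <- fit_direction(am_run)
  seg$al_dir_fit <- al_dir
  seg
}

#' Cross-section approach triangle
#'
#' Builds the classical right triangle of the proximal tibial cross-section:
#' the extension lines of the anteromedial and anterolateral cortical flats
#' and the tangent line of the posterior cortex.
#'
#' @param seg a [segment_cortex()] result.
#' @return list with `vertex_am_post`, `vertex_al_post`, `vertex_apex`,
#'   `right_angle_at` and the measured `angle_al_post_deg`.
#' @export
approach_triangle <- function(seg) {
  line_intersect <- function(p1, d1, p2, d2) {
    denom <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(denom) < 1e-12) abort("parallel construction lines", class = "tibtunnel_error_degenerate")
    t <- ((p2[1] - p1[1]) * d2[2] - (p2[2] - p1[2]) * d2[1]) / denom
    p1 + t * d1
  }
  am_d <- unit_vec(seg$am_flat[1, ] - seg$am_flat[2, ])
  al_d <- unit_vec(seg$al_flat[1, ] - seg$al_flat[2, ])
  tg <- seg$posterior_tangent
  if (is.null(tg)) abort("segmentation lacks a posterior tangent", class = "tibtunnel_error_degenerate")
  v_am <- line_intersect(seg$am_flat[2, ], am_d, tg$point, tg$dir)
  v_al <- line_intersect(seg$al_flat[2, ], al_d, tg$point, tg$dir)
  apex <- line_intersect(seg$am_flat[2, ], am_d, seg$al_flat[2, ], al_d)
  ang <- rad2deg(acos(abs(sum(unit_vec(apex - v_al) * unit_vec(v_am - v_al)))))
  list(vertex_am_post = v_am, vertex_al_post = v_al, vertex_apex = apex,
       right_angle_at = "vertex_al_post", angle_al_post_deg = ang)
}

#' Locate the five tunnel entry points on a cross-section
#'
#' T1: one third along the anteromedial flat from its anterior (crest-side)
#' end; T2: its midpoint; T3: the arc midpoint of the tibial crest; T4: one
#' third along the anterolateral flat from its anterior end; T5: its midpoint.
#'
#' @param seg a [segment_cortex()] or [cortex_segmentation()] object.
#' @return 5 x 2 matrix with rownames T1..T5.
#' @export
locate_entry_points <- function(seg) {
  flat_len <- function(run) sum(sqrt(rowSums((run[-1, , drop = FALSE] -
                                              run[-nrow(run), , drop = FALSE])^2)))
  if (flat_len(seg$am_run) < 1e-9 || flat_len(seg$al_run) < 1e-9) {
    abort("degenerate (zero-length) cortical flat", class = "tibtunnel_error_degenerate")
  }
  pts <- rbind(
    T1 = polyline_interp(seg$am_run, 1 / 3),
    T2 = polyline_interp(seg$am_run, 1 / 2),
    T3 = polyline_interp(seg$crest_pts, 1 / 2),
    T4 = polyline_interp(seg$al_run, 1 / 3),
    T5 = polyline_interp(seg$al_run, 1 / 2)
  )
  rownames(pts) <- c("T1", "T2", "T3", "T4", "T5")
  pts
}

#' Entry track of one approach along the anterior cortex
#'
#' @param approach one of `"T1"`..`"T5"`.
#' @param pts n x 3 matrix of on-surface points ordered proximal to distal
#'   (strictly decreasing z in the anatomical frame).
#' @param validate enforce the decreasing-z invariant; disable for tracks
#'   expressed in a rotated frame.
#' @return an object of class `entry_track`.
#' @export
entry_track <- function(approach, pts, validate = TRUE) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  if (validate && any(diff(pts[, 3]) >= 0)) {
    abort("entry track z must be strictly decreasing (proximal to distal)",
          class = "tibtunnel_error_params")
  }
  structure(list(approach = approach, pts = pts), class = "entry_track")
}

# interpolate a track at height z (linear between slices)
track_point_at_z <- function(track, z) {
  p <- track$pts
  zs <- p[, 3]
  if (z > zs[1] + 1e-9 || z < zs[length(zs)] - 1e-9) {
    abort(sprintf("z = %.3f outside track extent [%.3f, %.3f]",
                  z, zs[length(zs)], zs[1]),
          class = "tibtunnel_error_params")
  }
  j <- findInterval(-z, -zs, rightmost.closed = TRUE)
  j <- min(max(j, 1), nrow(p) - 1)
  w <- (zs[j] - z) / (zs[j] - zs[j + 1])
  (1 - w) * p[j, ] + w * p[j + 1, ]
}

#' Build the five entry tracks over an axial range
#'
#' Slices the mesh at regular axial levels, segments each cross-section and
#' chains the per-slice entry points into one polyline per approach. Track
#' identity across slices is kept by the fractional position along the flats,
#' which is stable under distal taper.
#'
#' @param mesh a [triangle_mesh()].
#' @param z_range length-2 numeric, proximal and distal slice levels (mm).
#' @param slice_step distance between slices (mm).
#' @param config a [segmentation_config()].
#' @return named list of five [entry_track()] objects (T1..T5).
#' @export
build_entry_tracks <- function(mesh, z_range, slice_step = 1,
                               config = segmentation_config()) {
  if (slice_step <= 0) abort("slice_step must be > 0", class = "tibtunnel_error_params")
  z_hi <- max(z_range); z_lo <- min(z_range)
  levels <- seq(z_hi, z_lo, by = -slice_step)
  per_level <- vector("list", length(levels))
  for (i in seq_along(levels)) {
    pts <- tryCatch({
      seg <- segment_cortex(slice_cross_section(mesh, levels[i]), config)
      locate_entry_points(seg)
    }, error = function(e) {
      abort(sprintf("entry-track construction failed at z = %.2f mm: %s",
                    levels[i], conditionMessage(e)),
            class = "tibtunnel_error_segmentation", parent = e)
    })
    per_level[[i]] <- pts
  }
  approaches <- c("T1", "T2", "T3", "T4", "T5")
  out <- lapply(approaches, function(a) {
    m <- t(vapply(seq_along(levels), function(i) per_level[[i]][a, ], numeric(2)))
    entry_track(a, cbind(m, levels))
  })
  names(out) <- approaches
  out
}
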