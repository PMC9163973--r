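#' Mesh resolution settings for the synthetic generator
#'
#' @param n_flat,n_crest,n_post sampling intervals on the cross-section regions
#'   (anteromedial flat, crest arc, anterolateral flat uses `n_flat`, posterior
#'   arc).
#' @param n_levels_top,n_levels_shaft wall subdivisions inside / below the
#'   proximal band (the band holds the facet and flare and is meshed finer).
#' @param top_band height of the finely meshed proximal band (mm).
#' @return a named list.
#' @export
mesh_resolution <- function(n_flat = 14, n_crest = 12, n_post = 30,
                            n_levels_top = 26, n_levels_shaft = 26,
                            top_band = 32) {
  list(n_flat = n_flat, n_crest = n_crest, n_post = n_post,
       n_levels_top = n_levels_top, n_levels_shaft = n_levels_shaft,
       top_band = top_band)
}

# Insert an extra vertex at medial-lateral position x_target on the posterior
# arc of an analytic profile, so the attachment centre lies on a mesh column.
insert_posterior_vertex <- function(profile, x_target) {
  ctr <- profile$post_center; r <- profile$post_radius
  if (abs(x_target) >= 0.98 * max(abs(profile$pts[profile$post_idx, 1]))) {
    abort("attachment_ml_offset falls outside the posterior arc",
          class = "tibtunnel_error_params")
  }
  y_target <- ctr[2] - sqrt(r^2 - (x_target - ctr[1])^2)
  post <- profile$pts[profile$post_idx, , drop = FALSE]
  # posterior arc runs lateral (x<0) to medial (x>0); x increases along it
  pos <- findInterval(x_target, post[, 1])
  if (pos < 1 || pos >= nrow(post)) {
    abort("attachment_ml_offset falls outside the posterior arc",
          class = "tibtunnel_error_params")
  }
  if (abs(post[pos, 1] - x_target) < 1e-9) {
    attach_idx <- profile$post_idx[pos]
  } else {
    insert_at <- profile$post_idx[pos]  # insert after this row
    profile$pts <- rbind(profile$pts[seq_len(insert_at), , drop = FALSE],
                         c(x_target, y_target),
                         profile$pts[-seq_len(insert_at), , drop = FALSE])
    profile$post_idx <- c(profile$post_idx[seq_len(pos)],
                          insert_at + 1L,
                          profile$post_idx[-seq_len(pos)] + 1L)
    attach_idx <- insert_at + 1L
  }
  profile$attach_idx <- attach_idx
  profile
}

#' Generate a synthetic proximal tibia with ground-truth landmarks
#'
#' Builds a watertight triangle mesh of the proximal tibia from analytic shape
#' parameters, together with the ground truth used to validate every
#' downstream stage: the PCL attachment centre (the tunnel exit point B), the
#' medial plateau rim, the analytic cortical flat lines per axial level, the
#' posterior cortex description and the true plateau-plane normal. The
#' generator is fully deterministic: identical parameters give byte-identical
#' meshes, and `global_scale` multiplies every coordinate exactly.
#'
#' @param params a [subject_params()] object (or a [shape_params()] object,
#'   which is wrapped with default covariates).
#' @param resolution a [mesh_resolution()] list.
#' @return a list with elements `mesh` ([triangle_mesh()]) and `landmarks`
#'   (class `ground_truth_landmarks`): `pcl_attachment_center`,
#'   `plateau_rim_curve`, `cortex_flat_params`, `posterior_cortex`,
#'   `true_plane_M_normal`, plus the scalar `global_scale` and `z_bottom`.
#' @export
#' @examples
#' sub <- generate_subject(subject_params())
#' sub$mesh
generate_subject <- function(params, resolution = mesh_resolution()) {
  if (inherits(params, "shape_params")) params <- subject_params(shape = params)
  if (!inherits(params, "subject_params")) {
    abort("params must be a subject_params or shape_params object",
          class = "tibtunnel_error_params")
  }
  shape <- validate_shape_params(params$shape)
  res <- resolution

  prof <- tibia_profile(shape, res$n_flat, res$n_crest, res$n_post)
  prof <- insert_posterior_vertex(prof, shape$attachment_ml_offset)
  pts <- prof$pts
  n_col <- nrow(pts)

  slope <- deg2rad(shape$plateau_posterior_slope)
  z_bot <- -shape$shaft_length
  a_d <- shape$attachment_depth
  g_free <- shape$attachment_facet_height - shape$attachment_depth

  # medial-lateral weighting of the attachment fossa along the posterior arc:
  # narrow, like the PCL footprint; outside it the posterior condylar
  # prominences take over
  bump <- numeric(n_col)
  post_x <- pts[prof$post_idx, 1]
  arc_span <- diff(range(post_x))
  u_pos <- (post_x - min(post_x)) / arc_span
  u_b <- (shape$attachment_ml_offset - min(post_x)) / arc_span
  bump[prof$post_idx] <- exp(-((u_pos - u_b) / 0.06)^2)
  is_post <- seq_len(n_col) %in% prof$post_idx

  # posterior offset profiles (mm, +y anterior): inside the fossa the facet
  # recedes anteriorly above B and the metaphyseal flare bulges posteriorly
  # below it, returning to the straight cortex at depth a_d + g_free; outside
  # the fossa the condylar prominences bulge posteriorly over the same band
  band <- a_d + g_free
  fossa_profile <- function(zeta) {
    out <- numeric(length(zeta))
    up <- zeta >= 0 & zeta < a_d
    out[up] <- shape$facet_inset * (1 - zeta[up] / a_d)
    lo <- zeta >= a_d & zeta <= band
    out[lo] <- -shape$flare_depth * sin(pi * (zeta[lo] - a_d) / g_free)
    out
  }
  band_c <- band + shape$condyle_drop      # condyles blend into the cortex
  condyle_profile <- function(zeta) {      # deeper than the fossa corner
    out <- numeric(length(zeta))
    inb <- zeta >= 0 & zeta <= band_c
    out[inb] <- -shape$condyle_depth * sin(pi * zeta[inb] / band_c)
    out
  }
  col_offset <- function(zeta) {
    (bump * fossa_profile(zeta) + (1 - bump) * condyle_profile(zeta)) * is_post
  }

  # condylar rounding: blend the cross-section toward its bounding ellipse
  # inside the plateau band so the plateau rim is convex (the triangular shaft
  # shape develops distally, as in real bones); zero below `round_h`
  ell_c <- c(mean(range(pts[, 1])), mean(range(pts[, 2])))
  ell_ab <- c(diff(range(pts[, 1])), diff(range(pts[, 2]))) / 2
  phi <- atan2(pts[, 2] - ell_c[2], pts[, 1] - ell_c[1])
  r_ell <- ell_ab[1] * ell_ab[2] /
    sqrt((ell_ab[2] * cos(phi))^2 + (ell_ab[1] * sin(phi))^2)
  ell_pts <- cbind(ell_c[1] + r_ell * cos(phi), ell_c[2] + r_ell * sin(phi))
  # cosine ramp: zero slope at the rim and at the band bottom, so the blended
  # wall never leans within the 45-degree upward cone used for rim extraction
  round_h <- 12; lambda_top <- 0.5
  morph_at <- function(zeta) {
    lambda_top * 0.5 * (1 + cos(pi * pmin(pmax(zeta / round_h, 0), 1)))
  }
  pts_eff <- function(lam) (1 - lam) * pts + lam * ell_pts

  top_xy <- pts_eff(lambda_top)
  y_top <- top_xy[, 2] + shape$facet_inset * bump
  z_top <- tan(slope) * y_top

  # graded wall levels: fine inside the proximal band holding facet + flare
  span_ref <- mean(z_top) - z_bot
  t_break <- 1 - res$top_band / span_ref
  t_levels <- c(seq(0, t_break, length.out = res$n_levels_shaft + 1),
                seq(t_break, 1, length.out = res$n_levels_top + 1)[-1])
  n_lev <- length(t_levels)

  taper_scale <- function(z) {
    shape$distal_taper + (1 - shape$distal_taper) * (z - z_bot) / (0 - z_bot)
  }

  # wall vertices: column-major blocks, one block per level
  verts <- matrix(NA_real_, n_col * n_lev, 3)
  for (k in seq_len(n_lev)) {
    zk <- z_bot + t_levels[k] * (z_top - z_bot)      # per-column level height
    s <- taper_scale(zk)
    zeta <- z_top - zk
    dy <- col_offset(zeta)
    p_eff <- pts_eff(morph_at(zeta))
    rows <- (k - 1) * n_col + seq_len(n_col)
    verts[rows, 1] <- s * p_eff[, 1]
    verts[rows, 2] <- s * p_eff[, 2] + dy
    verts[rows, 3] <- zk
  }

  idx <- function(i, k) (k - 1L) * n_col + ((i - 1L) %% n_col) + 1L
  i_seq <- seq_len(n_col)
  faces <- vector("list", n_lev - 1)
  for (k in seq_len(n_lev - 1)) {
    a <- idx(i_seq, k); b <- idx(i_seq + 1L, k)
    c_ <- idx(i_seq + 1L, k + 1L); d <- idx(i_seq, k + 1L)
    faces[[k]] <- rbind(cbind(a, b, c_), cbind(a, c_, d))
  }
  faces <- do.call(rbind, faces)

  # caps: bottom flat ring (level 1), top planar ring on the plateau plane;
  # ear-clipping handles the non-convex fossa notch in the plateau ring
  bot_ring <- idx(i_seq, 1L)
  top_ring <- idx(i_seq, n_lev)
  bot_tris <- triangulate_polygon(verts[bot_ring, 1:2, drop = FALSE])
  top_tris <- triangulate_polygon(verts[top_ring, 1:2, drop = FALSE])
  bot_faces <- cbind(bot_ring[bot_tris[, 1]], bot_ring[bot_tris[, 3]],
                     bot_ring[bot_tris[, 2]])                 # downward normal
  top_faces <- cbind(top_ring[top_tris[, 1]], top_ring[top_tris[, 2]],
                     top_ring[top_tris[, 3]])                 # upward normal
  faces <- rbind(faces, bot_faces, top_faces)

  mesh <- triangle_mesh(verts, faces, validate = FALSE)
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]

  # attachment centre B on the wall column through attachment_ml_offset,
  # interpolated along a mesh edge so it lies exactly on the surface
  i_b <- prof$attach_idx
  z_b <- z_top[i_b] - a_d
  col_rows <- idx(i_b, seq_len(n_lev))
  col_z <- verts[col_rows, 3]
  k_lo <- max(which(col_z <= z_b + 1e-12))
  k_lo <- min(k_lo, n_lev - 1L)
  wv <- (z_b - col_z[k_lo]) / (col_z[k_lo + 1] - col_z[k_lo])
  b_point <- (1 - wv) * verts[col_rows[k_lo], ] + wv * verts[col_rows[k_lo + 1], ]

  # medial plateau rim: contiguous top-ring arc with x > 0, anterior first
  ring <- verts[idx(i_seq, n_lev), , drop = FALSE]
  med <- which(ring[, 1] > 0)
  if (length(med) < 4) abort("degenerate medial rim", class = "tibtunnel_error_mesh")
  breaks <- which(diff(med) > 1)
  if (length(breaks)) med <- c(med[(breaks[1] + 1):length(med)], med[seq_len(breaks[1])])
  rim <- ring[med, , drop = FALSE]

  gs <- params$global_scale
  landmarks <- structure(list(
    pcl_attachment_center = b_point * gs,
    plateau_rim_curve = rim * gs,
    cortex_flat_params = list(
      am = list(point = prof$am_line$point * gs, dir = prof$am_line$dir,
                anterior_end = prof$am_line$anterior_end * gs,
                posterior_end = prof$am_line$posterior_end * gs),
      al = list(point = prof$al_line$point * gs, dir = prof$al_line$dir,
                anterior_end = prof$al_line$anterior_end * gs,
                posterior_end = prof$al_line$posterior_end * gs),
      taper = shape$distal_taper, z_bottom = z_bot * gs
    ),
    posterior_cortex = list(
      circle_center = prof$post_center * gs, circle_radius = prof$post_radius * gs,
      sagitta = prof$sagitta * gs,
      attachment_depth = a_d * gs, free_height = g_free * gs,
      flare_depth = shape$flare_depth * gs, facet_inset = shape$facet_inset * gs,
      attachment_column_x = shape$attachment_ml_offset * gs
    ),
    true_plane_M_normal = c(0, -sin(slope), cos(slope)),
    profile_area = prof$area,           # unscaled analytic area at plateau level
    global_scale = gs,
    z_bottom = z_bot * gs,
    z_top_range = range(z_top) * gs
  ), class = "ground_truth_landmarks")

  mesh$vertices <- mesh$vertices * gs
  list(mesh = mesh, landmarks = landmarks)
}

# Analytic in-plane scale factor of the cross-section at height z (before
# global scaling); exported for tests through ground truth.
profile_scale_at <- function(landmarks, z) {
  gt <- landmarks$cortex_flat_params
  gs <- landmarks$global_scale
  zb <- gt$z_bottom
  gt$taper + (1 - gt$taper) * (z - zb) / (0 - zb) * 1
}

#' Sample a synthetic cohort
#'
#' Draws `n` subjects from the population distributions: sex from the
#' configured ratio, age uniform over the configured range, height normal per
#' sex (truncated to plausible stature), `global_scale` from the affine
#' height map, and shape parameters jittered around the population means with
#' the configured coefficient of variation. Reproducible for a fixed seed.
#'
#' @param n number of subjects (>= 1).
#' @param seed integer RNG seed.
#' @param config a [population_config()].
#' @return a list of [subject_params()] objects.
#' @export
#' @examples
#' cohort <- sample_cohort(3, seed = 1)
#' vapply(cohort, function(s) s$height, numeric(1))
sample_cohort <- function(n, seed = 1L, config = population_config()) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("n must be a positive count", class = "tibtunnel_error_params")
  }
  if (!inherits(config, "population_config")) {
    abort("config must be a population_config object", class = "tibtunnel_error_params")
  }
  n <- as.integer(n)
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))

  base <- config$base_shape
  jitter_mult <- function(x, cv) x * (1 + pmax(pmin(rnorm(1, 0, cv), 2.5 * cv), -2.5 * cv))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sex <- if (runif(1) < config$male_fraction) "male" else "female"
    age <- runif(1, config$age_range[1], config$age_range[2])
    h <- rnorm(1, config$height_mean[[sex]], config$height_sd[[sex]])
    h <- min(max(h, 1.40), 1.98)
    gsc <- config$scale_intercept + config$scale_slope * h
    cv <- config$shape_cv
    shp <- base
    shp$posterior_width <- jitter_mult(base$posterior_width, cv)
    shp$am_cortex_angle <- jitter_mult(base$am_cortex_angle, cv)
    shp$al_cortex_angle <- min(90, jitter_mult(base$al_cortex_angle, cv / 2))
    shp$crest_radius <- jitter_mult(base$crest_radius, cv)
    # jitter the posterior sagitta, not ap_depth directly: the crest height
    # depends on the width and angles drawn above
    base_sag <- base$ap_depth - profile_crest_height(base)
    shp$ap_depth <- profile_crest_height(shp) +
      max(0.5, jitter_mult(base_sag, 1.5 * cv))
    shp$attachment_depth <- jitter_mult(base$attachment_depth, cv)
    shp$attachment_facet_height <- shp$attachment_depth +
      jitter_mult(base$attachment_facet_height - base$attachment_depth, 1.6 * cv)
    shp$attachment_ml_offset <- base$attachment_ml_offset + rnorm(1, 0, 1.5)
    shp$plateau_posterior_slope <- base$plateau_posterior_slope + rnorm(1, 0, 1.2)
    shp$flare_depth <- jitter_mult(base$flare_depth, cv)
    ok <- tryCatch({ validate_shape_params(shp); TRUE }, error = function(e) FALSE)
    if (!ok) shp <- base  # extremely rare; fall back to the population mean
    out[[i]] <- subject_params(
      subject_id = sprintf("S%03d", i), sex = sex, age = age, height = h,
      global_scale = gsc, shape = shp, seed = as.integer(seed) + i
    )
  }
  out
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
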