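# Analytic 2D cross-section profile of the proximal tibial shaft: two straight
# cortical flats (anteromedial, anterolateral) joined anteriorly by the rounded
# tibial crest and posteriorly by a shallow arc tangent to the posterior
# cortex line. Coordinates: x medial, y anterior; the posterior tangent chord
# of the flats lies on y = 0 and the posterior arc sags to y = -sagitta.

#' Analytic cross-section profile of the tibial shaft
#'
#' Builds the rounded-triangle outline used at every axial level of the
#' synthetic tibia, together with the analytic parameters (flat lines, crest
#' arc, posterior arc) that serve as ground truth for the landmarking stages.
#'
#' @param shape a [shape_params()] object.
#' @param n_flat,n_crest,n_post number of sampling intervals on each flat, the
#'   crest arc, and the posterior arc.
#' @return a list with elements `pts` (closed CCW polygon, one row per vertex,
#'   first vertex not repeated), region index vectors (`am_idx`, `crest_idx`,
#'   `al_idx`, `post_idx`), analytic entries `am_line`/`al_line` (each a list
#'   with `point`, `dir`, `anterior_end`, `posterior_end`), `apex`,
#'   `crest_center`, `crest_radius`, `crest_top`, `post_center`, `post_radius`,
#'   `sagitta`, and the closed-form `area`.
# Height of the rounded crest above the flats' posterior chord (y = 0),
# without requiring a valid ap_depth; used by the cohort sampler to keep
# jittered parameters geometrically consistent.
profile_crest_height <- function(shape) {
  w <- shape$posterior_width
  am <- deg2rad(shape$am_cortex_angle)
  al <- deg2rad(shape$al_cortex_angle)
  rc <- shape$crest_radius
  p_am <- c(w / 2, 0); p_al <- c(-w / 2, 0)
  y_apex <- w / (1 / tan(am) + 1 / tan(al))
  apex <- c(w / 2 - y_apex / tan(am), y_apex)
  gam <- pi - am - al
  t_c <- rc / tan(gam / 2)
  d_am <- unit_vec(p_am - apex); d_al <- unit_vec(p_al - apex)
  ctr <- apex + (rc / sin(gam / 2)) * unit_vec(d_am + d_al)
  tang <- rbind(apex + t_c * d_am, apex + t_c * d_al)
  a1 <- atan2(tang[1, 2] - ctr[2], tang[1, 1] - ctr[1])
  a2 <- atan2(tang[2, 2] - ctr[2], tang[2, 1] - ctr[1])
  if (a2 < a1) a2 <- a2 + 2 * pi
  # arc top is the circle top if pi/2 lies in the swept range, else an endpoint
  tops <- tang[, 2]
  if ((a1 <= pi / 2 && pi / 2 <= a2) || (a1 <= 5 * pi / 2 && 5 * pi / 2 <= a2)) {
    tops <- c(tops, ctr[2] + rc)
  }
  max(tops)
}

#' @keywords internal
tibia_profile <- function(shape, n_flat = 14, n_crest = 12, n_post = 30) {
  w <- shape$posterior_width
  am <- deg2rad(shape$am_cortex_angle)
  al <- deg2rad(shape$al_cortex_angle)
  rc <- shape$crest_radius

  p_am <- c(w / 2, 0)    # posterior end of the AM flat (medial)
  p_al <- c(-w / 2, 0)   # posterior end of the AL flat (lateral)

  y_apex <- w / (1 / tan(am) + 1 / tan(al))
  apex <- c(w / 2 - y_apex / tan(am), y_apex)

  gam <- pi - am - al                      # interior angle at the apex
  t_c <- rc / tan(gam / 2)                 # apex-to-tangency distance
  d_am <- unit_vec(p_am - apex)
  d_al <- unit_vec(p_al - apex)
  if (t_c > 0.9 * min(vec_norm(p_am - apex), vec_norm(p_al - apex))) {
    abort("invalid shape parameters: crest_radius too large for the triangle",
          class = "tibtunnel_error_params")
  }
  tang_am <- apex + t_c * d_am
  tang_al <- apex + t_c * d_al
  crest_center <- apex + (rc / sin(gam / 2)) * unit_vec(d_am + d_al)

  # crest arc from tang_am to tang_al passing anterior of the centre
  a1 <- atan2(tang_am[2] - crest_center[2], tang_am[1] - crest_center[1])
  a2 <- atan2(tang_al[2] - crest_center[2], tang_al[1] - crest_center[1])
  # sweep counterclockwise in polygon order (medial -> anterior -> lateral),
  # i.e. increasing angle from a1 to a2
  if (a2 < a1) a2 <- a2 + 2 * pi
  crest_ang <- seq(a1, a2, length.out = n_crest + 1)
  crest_pts <- cbind(crest_center[1] + rc * cos(crest_ang),
                     crest_center[2] + rc * sin(crest_ang))
  crest_top <- max(crest_pts[, 2])

  sagitta <- shape$ap_depth - crest_top
  if (sagitta <= 0.2) {
    abort(paste0("invalid shape parameters: ap_depth (", format(shape$ap_depth),
                 ") must exceed the rounded crest height (", format(round(crest_top, 2)),
                 ") by more than 0.2 mm"),
          class = "tibtunnel_error_params")
  }
  r_post <- ((w / 2)^2 + sagitta^2) / (2 * sagitta)
  post_center <- c(0, r_post - sagitta)
  b1 <- atan2(0 - post_center[2], p_al[1])   # angle of p_al (just below -pi/2)
  b2 <- atan2(0 - post_center[2], p_am[1])   # angle of p_am (just above -pi/2)
  # posterior arc from p_al to p_am passes through (0, -sagitta) at angle
  # -pi/2; the short increasing sweep b1 -> b2 is the correct (CCW) branch
  if (b2 < b1) b2 <- b2 + 2 * pi
  post_ang <- seq(b1, b2, length.out = n_post + 1)
  post_pts <- cbind(post_center[1] + r_post * cos(post_ang),
                    post_center[2] + r_post * sin(post_ang))

  am_flat <- cbind(seq(p_am[1], tang_am[1], length.out = n_flat + 1),
                   seq(p_am[2], tang_am[2], length.out = n_flat + 1))

  al_flat <- cbind(seq(tang_al[1], p_al[1], length.out = n_flat + 1),
                   seq(tang_al[2], p_al[2], length.out = n_flat + 1))

  # assemble CCW polygon: AM flat (posterior->anterior), crest arc, AL flat
  # (anterior->posterior), posterior arc (lateral->medial); drop duplicated
  # junction vertices
  pts <- rbind(am_flat,
               crest_pts[-1, , drop = FALSE],
               al_flat[-1, , drop = FALSE],
               post_pts[-c(1, nrow(post_pts)), , drop = FALSE])
  n_am <- nrow(am_flat)
  n_cr <- nrow(crest_pts) - 1
  n_al <- nrow(al_flat) - 1
  n_po <- nrow(post_pts) - 2
  am_idx <- seq_len(n_am)
  crest_idx <- n_am + seq_len(n_cr)
  al_idx <- n_am + n_cr + seq_len(n_al)
  post_idx <- n_am + n_cr + n_al + seq_len(n_po)

  # closed-form area: triangle minus crest corner cut plus posterior segment
  tri_area <- w * y_apex / 2
  corner_cut <- rc^2 * (1 / tan(gam / 2) - (pi - gam) / 2)
  seg_ang <- 2 * asin(pmin(1, (w / 2) / r_post))
  post_segment <- r_post^2 / 2 * (seg_ang - sin(seg_ang))
  area <- tri_area - corner_cut + post_segment

  list(
    pts = pts,
    am_idx = am_idx, crest_idx = crest_idx, al_idx = al_idx, post_idx = post_idx,
    am_line = list(point = p_am, dir = unit_vec(apex - p_am),
                   anterior_end = tang_am, posterior_end = p_am),
    al_line = list(point = p_al, dir = unit_vec(apex - p_al),
                   anterior_end = tang_al, posterior_end = p_al),
    apex = apex, crest_center = crest_center, crest_radius = rc,
    crest_top = crest_top, post_center = post_center, post_radius = r_post,
    sagitta = sagitta, area = area
  )
}
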