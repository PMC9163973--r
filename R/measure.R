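#' Permissive safe angle of a tunnel against plane M
#'
#' The PSA is the angle between the tunnel centreline and the medial plateau
#' plane, computed in closed form as `asin(|axis . normal|)`. The classical
#' witness construction is also built: plane N contains the centreline and is
#' perpendicular to plane M; S is the centreline-plane intersection, P a point
#' on the M-N intersection line, and the angle A-S-P equals the PSA.
#'
#' @param tunnel a [solve_max_angle_tunnel()] result, or any list with
#'   `entry_A`, `exit_B` fields.
#' @param plane_M a [plateau_plane()].
#' @return list with `psa_deg` and `witness` (S, P, `plane_N_normal`,
#'   `angle_asp_deg`, `degenerate` flag).
#' @export
compute_psa <- function(tunnel, plane_M) {
  a <- tunnel$entry_A; b <- tunnel$exit_B
  axis_raw <- b - a
  len <- vec_norm(axis_raw)
  if (len < 1e-12) abort("zero-length tunnel axis", class = "tibtunnel_error_degenerate")
  u <- axis_raw / len
  n <- plane_M$normal
  s_ang <- abs(sum(u * n))
  psa <- rad2deg(asin(min(1, s_ang)))

  # witness: S = centreline cut with plane M; P along the projected direction
  denom <- sum(u * n)
  degenerate <- FALSE
  if (abs(denom) < 1e-12) {
    # axis parallel to the plane: take S as the projection of A
    S <- a - sum((a - plane_M$E) * n) * n
  } else {
    t <- sum((plane_M$E - a) * n) / denom
    S <- a + t * u
  }
  w <- u - sum(u * n) * n
  if (vec_norm(w) < 1e-9) {
    degenerate <- TRUE                       # vertical tunnel: PSA = 90
    w <- cross3(n, if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
  }
  w <- unit_vec(w)
  P <- S + 10 * w
  n_N <- cross3(u, n)
  if (vec_norm(n_N) < 1e-12) n_N <- cross3(w, n)
  n_N <- unit_vec(n_N)
  # the ray S->A lies along the centreline, so the angle A-S-P is the acute
  # angle between the axis and the projected direction; this form also covers
  # an entry point lying exactly on plane M (A = S)
  angle_asp <- rad2deg(acos(pmin(1, pmax(-1, abs(sum(u * w))))))
  list(psa_deg = psa,
       witness = list(S = S, P = P, plane_N_normal = n_N,
                      angle_asp_deg = angle_asp, degenerate = degenerate))
}

#' Tibial tunnel height: distance from the entry point to plane M
#'
#' @param entry_A entry point (mm).
#' @param plane_M a [plateau_plane()].
#' @return unsigned distance (mm); the signed value (negative below the plane)
#'   is attached as attribute `signed`.
#' @export
compute_tth <- function(entry_A, plane_M) {
  s <- sum((entry_A - plane_M$E) * plane_M$normal)
  structure(abs(s), signed = s)
}

#' Tibial tunnel depth: entry-to-exit length of the centreline
#'
#' @param entry_A,exit_B tunnel endpoints (mm).
#' @return Euclidean distance (mm).
#' @export
compute_ttd <- function(entry_A, exit_B) {
  vec_norm(exit_B - entry_A)
}

#' Measure a solved tunnel
#'
#' @param tunnel a [solve_max_angle_tunnel()] result.
#' @param plane_M a [plateau_plane()].
#' @param subject_id identifier copied into the record.
#' @return one-row tibble: `subject_id`, `approach`, `psa_deg`, `tth_mm`,
#'   `ttd_mm`, `clearance_mm`, `converged`.
#' @export
measure_tunnel <- function(tunnel, plane_M, subject_id = NA_character_) {
  psa <- compute_psa(tunnel, plane_M)
  tibble(
    subject_id = subject_id,
    approach = tunnel$approach,
    psa_deg = psa$psa_deg,
    tth_mm = as.numeric(compute_tth(tunnel$entry_A, plane_M)),
    ttd_mm = compute_ttd(tunnel$entry_A, tunnel$exit_B),
    clearance_mm = if (!is.null(tunnel$clearance)) tunnel$clearance else NA_real_,
    converged = if (!is.null(tunnel$converged)) tunnel$converged else NA
  )
}
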