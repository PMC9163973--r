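# Shared fixtures, built once per test run. The default subject and its
# derived pipeline objects are used across several test files.

.pipeline_cache <- new.env(parent = emptyenv())

default_pipeline <- function() {
  if (is.null(.pipeline_cache$default)) {
    sub <- generate_subject(subject_params())
    mesh <- sub$mesh
    plane_m <- fit_plane_M(extract_medial_rim(mesh))
    tracks <- build_entry_tracks(mesh, c(-24, -95), slice_step = 1)
    samples <- posterior_cortex_samples(mesh, sub$landmarks$pcl_attachment_center,
                                        radius = 5, plane_M = plane_m)
    .pipeline_cache$default <- list(
      subject = sub, mesh = mesh, landmarks = sub$landmarks,
      exit_B = sub$landmarks$pcl_attachment_center,
      plane_M = plane_m, tracks = tracks, samples = samples
    )
  }
  .pipeline_cache$default
}

solve_approach <- function(pl, approach, radius = 5) {
  spec <- tunnel_spec(pl$exit_B, pl$tracks[[approach]], radius = radius)
  solve_max_angle_tunnel(pl$mesh, spec, pl$plane_M, samples = pl$samples)
}

# idealized right triangle used in the cross-section examples: legs from the apex
# (0, 40) to (-30, 0) and (0, 0), posterior edge on y = 0
toy_triangle_segmentation <- function() {
  cortex_segmentation(
    am_flat = rbind(c(0, 40), c(-30, 0)),
    al_flat = rbind(c(0, 40), c(0, 0)),
    posterior_tangent = list(point = c(0, 0), dir = c(1, 0))
  )
}

random_rigid_motion <- function() {
  axis <- rnorm(3)
  angle <- runif(1, 0.1, 1.5)
  list(R = rotation_matrix(axis, angle), t = rnorm(3, 0, 25))
}

# brute-force geometric circle fit by coarse-to-fine grid search; independent
# oracle for fit_circle_2d
grid_circle_fit <- function(xy, span = 5, steps = 3) {
  obj <- function(cx, cy, r) sum((sqrt((xy[, 1] - cx)^2 + (xy[, 2] - cy)^2) - r)^2)
  cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
  r <- mean(sqrt((xy[, 1] - cx)^2 + (xy[, 2] - cy)^2))
  width <- span
  for (s in seq_len(steps + 4)) {
    grid <- expand.grid(cx = cx + seq(-width, width, length.out = 11),
                        cy = cy + seq(-width, width, length.out = 11),
                        r = r + seq(-width, width, length.out = 11))
    vals <- mapply(obj, grid$cx, grid$cy, grid$r)
    best <- grid[which.min(vals), ]
    cx <- best$cx; cy <- best$cy; r <- best$r
    width <- width / 4
  }
  list(center = c(cx, cy), radius = r)
}

rotate2d <- function(xy, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  xy %*% t(R)
}

# mirror a mesh across the sagittal plane, flipping winding to stay outward
mesh_mirror_x_test <- function(mesh) {
  v <- mesh$vertices; v[, 1] <- -v[, 1]
  triangle_mesh(v, mesh$faces[, c(1, 3, 2)], validate = FALSE)
}
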