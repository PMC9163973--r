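test_that("posterior cortex sampling is on-surface, dense, and respects exclusion", {
  fx <- make_slab_fixture(m = 10)
  smp <- posterior_cortex_samples(fx$mesh, fx$exit_B, exclusion_radius = 0,
                                  plane_M = fx$plane_M)
  expect_true(all(abs(smp[, 2]) < 1e-9))          # slab cortex is the plane y = 0
  expect_true(all(smp[, 3] <= -10 + 1e-9))

  pl <- default_pipeline()
  # samples lie on the mesh surface: each is on the supporting plane of one
  # of its nearby faces
  sub <- pl$samples[seq(1, nrow(pl$samples), length.out = 150), ]
  fc <- mesh_face_centroids(pl$mesh)
  fn <- mesh_face_normals(pl$mesh)
  v1 <- pl$mesh$vertices[pl$mesh$faces[, 1], , drop = FALSE]
  worst <- 0
  for (i in seq_len(nrow(sub))) {
    p <- sub[i, ]
    near <- order(rowSums(sweep(fc, 2, p)^2))[1:12]
    d <- min(abs(rowSums((matrix(p, 12, 3, byrow = TRUE) - v1[near, , drop = FALSE]) *
                           fn[near, , drop = FALSE])))
    worst <- max(worst, d)
  }
  expect_lt(worst, 1e-9)
  # exclusion ball honoured
  db <- sqrt(rowSums(sweep(pl$samples, 2, pl$exit_B)^2))
  expect_true(all(db > 6))
  # density: sample count at least 4 per mm^2 of kept posterior area
  expect_gt(nrow(pl$samples), 4000)

  expect_warning(posterior_cortex_samples(fx$mesh, fx$exit_B,
                                          exclusion_radius = 1e4,
                                          plane_M = fx$plane_M),
                 "exclusion")
})

test_that("clearance matches closed-form points and a brute-force loop", {
  spec <- tunnel_spec(exit_B = c(0, 0, 60), radius = 5,
                      track = entry_track("T3", cbind(0, 20, seq(0, -10))))
  # axis along z through the origin, single sample at distance 8: clearance 3
  expect_equal(clearance(c(0, 0, 0), spec, matrix(c(8, 0, 30), 1)), 3,
               tolerance = 1e-12)
  # sample exactly on the cylinder surface: clearance 0
  expect_equal(clearance(c(0, 0, 0), spec, matrix(c(5, 0, 30), 1)), 0,
               tolerance = 1e-12)

  set.seed(7)
  pts <- matrix(rnorm(3000, 0, 40), ncol = 3)
  a <- c(3, -9, 2); b <- c(-20, 14, 55)
  fast <- point_segment_distance(pts, a, b)
  slow <- apply(pts, 1, function(p) {
    ab <- b - a
    t <- max(0, min(1, sum((p - a) * ab) / sum(ab^2)))
    sqrt(sum((p - (a + t * ab))^2))
  })
  expect_lt(max(abs(fast - slow)), 1e-12)

  expect_error(clearance(c(0, 0, 0), spec, matrix(numeric(0), ncol = 3)),
               class = "tibtunnel_error_params")
  expect_error(clearance(c(0, 0, 60), spec, matrix(1, 1, 3)),
               class = "tibtunnel_error_degenerate")
})

test_that("slab tangency matches arccos(r/m) and boundary cases are infeasible", {
  for (m in c(7.5, 10, 12.5, 20)) {
    fx <- make_slab_fixture(m = m)
    spec <- tunnel_spec(fx$exit_B, fx$track, radius = 5)
    tun <- solve_max_angle_tunnel(fx$mesh, spec, fx$plane_M,
                                  exclusion_radius = fx$exclusion_radius)
    expect_true(tun$converged)
    expect_gte(tun$clearance, 0)
    expect_lte(tun$clearance, spec$clearance_tol)
    expect_lt(abs(tun$psa_deg - acos(5 / m) * 180 / pi), 0.5)
  }
  fx5 <- make_slab_fixture(m = 5)
  expect_error(
    solve_max_angle_tunnel(fx5$mesh, tunnel_spec(fx5$exit_B, fx5$track, radius = 5),
                           fx5$plane_M, exclusion_radius = 0),
    class = "tibtunnel_error_infeasible"
  )
})

test_that("slab PSA increases with free height and decreases with radius", {
  psa_at <- function(m, r) {
    fx <- make_slab_fixture(m = m)
    solve_max_angle_tunnel(fx$mesh, tunnel_spec(fx$exit_B, fx$track, radius = r),
                           fx$plane_M, exclusion_radius = 0)$psa_deg
  }
  p1 <- psa_at(8, 5); p2 <- psa_at(11, 5); p3 <- psa_at(14, 5)
  expect_true(p1 < p2 && p2 < p3)
  q1 <- psa_at(12, 4); q2 <- psa_at(12, 6)
  expect_true(q1 > q2)
})

test_that("solved tunnels are tangent and refinement-stable on the tibia", {
  pl <- default_pipeline()
  for (a in c("T1", "T3", "T5")) {
    tun <- solve_approach(pl, a)
    expect_true(tun$converged)
    expect_true(tun$monotone)
    expect_gte(tun$clearance, 0)
    expect_lte(tun$clearance, 0.05)
    # entry on the track
    expect_lt(min(point_polyline_distance(matrix(tun$entry_A, 1),
                                          pl$tracks[[a]]$pts)), 0.1)
  }
  # halving sample density and bisection tolerance moves PSA by < 0.2 degrees
  spec <- tunnel_spec(pl$exit_B, pl$tracks$T1, radius = 5)
  coarse_smp <- posterior_cortex_samples(pl$mesh, pl$exit_B, radius = 5,
                                         plane_M = pl$plane_M, density = 2)
  tun_ref <- solve_approach(pl, "T1")
  tun_coarse <- solve_max_angle_tunnel(pl$mesh, spec, pl$plane_M,
                                       samples = coarse_smp, z_tol = 0.02)
  expect_lt(abs(tun_ref$psa_deg - tun_coarse$psa_deg), 0.2)
})

test_that("solution is invariant under rigid motion of mesh and landmarks", {
  pl <- default_pipeline()
  set.seed(31)
  mot <- random_rigid_motion()
  mesh_r <- mesh_transform(pl$mesh, mot$R, mot$t)
  b_r <- as.vector(mot$R %*% pl$exit_B + mot$t)
  pm <- pl$plane_M
  pm_r <- plateau_plane(as.vector(mot$R %*% pm$E + mot$t),
                        as.vector(mot$R %*% pm$F + mot$t),
                        as.vector(mot$R %*% pm$G + mot$t),
                        as.vector(mot$R %*% pm$normal))
  smp_r <- posterior_cortex_samples(mesh_r, b_r, radius = 5, plane_M = pm_r,
                                    posterior = as.vector(mot$R %*% c(0, -1, 0)))
  for (a in c("T2", "T4")) {
    t0 <- solve_approach(pl, a)
    track_r <- entry_track(a, apply_rigid(pl$tracks[[a]]$pts, mot$R, mot$t),
                           validate = FALSE)
    t_r <- solve_max_angle_tunnel(mesh_r, tunnel_spec(b_r, track_r, radius = 5),
                                  pm_r, samples = smp_r)
    expect_lt(abs(t_r$psa_deg - t0$psa_deg), 0.1)
    m0 <- measure_tunnel(t0, pm); m_r <- measure_tunnel(t_r, pm_r)
    expect_lt(abs(m_r$tth_mm - m0$tth_mm), 0.01)
    expect_lt(abs(m_r$ttd_mm - m0$ttd_mm), 0.01)
  }
})

test_that("tunnel_spec validates its inputs", {
  pl <- default_pipeline()
  expect_error(tunnel_spec(pl$exit_B, pl$tracks$T1, radius = 0),
               class = "tibtunnel_error_params")
  expect_error(tunnel_spec(pl$exit_B, pl$tracks$T1, search_z = c(-500, -400)),
               class = "tibtunnel_error_params")
})
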