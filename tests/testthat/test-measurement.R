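cross3v <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
cross3_test <- function(n) {
  v <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- cross3v(n, v)
  w / sqrt(sum(w^2))
}

plane_z0 <- plateau_plane(E = c(0, 20, 0), F_pt = c(20, 0, 0), G = c(0, -20, 0),
                          normal = c(0, 0, 1))

test_that("PSA closed form handles parallel, perpendicular and oblique axes", {
  mk <- function(a, b) list(entry_A = a, exit_B = b, approach = "T1")
  expect_equal(compute_psa(mk(c(0, 0, 0), c(10, 5, 0)), plane_z0)$psa_deg, 0,
               tolerance = 1e-12)
  p90 <- compute_psa(mk(c(0, 0, -30), c(0, 0, 0)), plane_z0)
  expect_equal(p90$psa_deg, 90, tolerance = 1e-12)
  expect_true(p90$witness$degenerate)
  expect_equal(compute_psa(mk(c(0, 0, 0), c(0, 1, 1)), plane_z0)$psa_deg, 45,
               tolerance = 1e-9)
  expect_error(compute_psa(mk(c(1, 1, 1), c(1, 1, 1)), plane_z0),
               class = "tibtunnel_error_degenerate")
})

test_that("the angle-ASP witness construction equals the arcsin formula", {
  set.seed(5)
  for (i in 1:25) {
    a <- rnorm(3, 0, 30); b <- rnorm(3, 0, 30)
    n <- rnorm(3); n <- n / sqrt(sum(n^2)); if (n[3] <= 0) n <- -n
    e1 <- cross3_test(n); e2 <- cross3v(n, e1)
    pm <- plateau_plane(E = 10 * e1, F_pt = 10 * e2, G = -7 * e1 + 3 * e2,
                        normal = n)
    res <- compute_psa(list(entry_A = a, exit_B = b), pm)
    if (!res$witness$degenerate) {
      expect_equal(res$witness$angle_asp_deg, res$psa_deg, tolerance = 1e-9)
      # S on plane M, plane N normal perpendicular to plane M's normal
      expect_lt(abs(sum((res$witness$S - pm$E) * pm$normal)), 1e-7)
      expect_lt(abs(sum(res$witness$plane_N_normal * pm$normal)), 1e-9)
      u <- (b - a) / sqrt(sum((b - a)^2))
      expect_lt(abs(sum(res$witness$plane_N_normal * u)), 1e-9)
    }
  }
})

test_that("TTH is an unsigned point-plane distance validated by a grid oracle", {
  expect_equal(as.numeric(compute_tth(c(3, 4, 0), plane_z0)), 0, tolerance = 1e-12)
  expect_equal(as.numeric(compute_tth(c(0, 0, -50), plane_z0)), 50, tolerance = 1e-12)

  set.seed(9)
  p1 <- rnorm(3, 0, 10); p2 <- rnorm(3, 0, 10); p3 <- rnorm(3, 0, 10)
  n <- cross3v(p2 - p1, p3 - p1); n <- n / sqrt(sum(n^2)); if (n[3] <= 0) n <- -n
  pm <- plateau_plane(p1, p2, p3, n)
  a <- rnorm(3, 0, 20)
  # dense grid over the plane as an independent oracle for min distance:
  # coarse pass over the whole patch, fine pass around the coarse argmin
  e1 <- (p2 - p1) / sqrt(sum((p2 - p1)^2)); e2 <- cross3v(n, e1)
  grid_min <- function(uc, vc, half, by) {
    g <- as.matrix(expand.grid(u = uc + seq(-half, half, by = by),
                               v = vc + seq(-half, half, by = by)))
    pts <- sweep(outer(g[, 1], e1) + outer(g[, 2], e2), 2, -p1)
    i <- which.min(rowSums(sweep(pts, 2, a)^2))
    list(d = sqrt(sum((pts[i, ] - a)^2)), u = g[i, 1], v = g[i, 2])
  }
  coarse <- grid_min(0, 0, 120, 2)
  fine <- grid_min(coarse$u, coarse$v, 2.5, 0.005)
  expect_lt(abs(as.numeric(compute_tth(a, pm)) - fine$d), 1e-3)
})

test_that("TTD is Euclidean and the right-triangle identity holds on solver output", {
  expect_equal(compute_ttd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(compute_ttd(c(0, 0, 0), c(3, 4, 12)), 13, tolerance = 1e-12)

  # with B moved onto plane M, TTD * sin(PSA) = TTH exactly
  pl <- default_pipeline()
  tun <- solve_approach(pl, "T2")
  pm <- pl$plane_M
  b_proj <- tun$exit_B - sum((tun$exit_B - pm$E) * pm$normal) * pm$normal
  fake <- list(entry_A = tun$entry_A, exit_B = b_proj, approach = "T2")
  psa <- compute_psa(fake, pm)$psa_deg
  tth <- as.numeric(compute_tth(tun$entry_A, pm))
  ttd <- compute_ttd(tun$entry_A, b_proj)
  expect_lt(abs(ttd * sin(psa * pi / 180) - tth), 1e-6)
})

test_that("measurements obey the scale law end to end", {
  cfg <- run_config()
  r1 <- measure_subject(subject_params(), cfg)
  r2 <- measure_subject(subject_params(global_scale = 1.2),
                        scale_run_config(cfg, 1.2))
  expect_lt(max(abs(r2$psa_deg - r1$psa_deg)), 0.1)
  expect_lt(max(abs(r2$tth_mm / r1$tth_mm - 1.2)) / 1.2, 1e-6)
  expect_lt(max(abs(r2$ttd_mm / r1$ttd_mm - 1.2)) / 1.2, 1e-6)
  expect_true(all(r1$converged))
  expect_true(all(r1$psa_deg >= 0 & r1$psa_deg <= 90))
  expect_true(all(r1$ttd_mm >= r1$tth_mm - 7))   # B sits below plane M
})

cross3_test <- function(n) {
  v <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- cross3v(n, v)
  w / sqrt(sum(w^2))
}
cross3v <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
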