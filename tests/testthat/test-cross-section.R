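test_that("slicing recovers analytic solids and reports empty slices", {
  cube <- make_box_mesh(c(0, 1), c(0, 1), c(0, 1), grid = 0.5)
  sq <- slice_cross_section(cube, 0.5)
  expect_equal(abs(polygon_signed_area(sq$polygon)), 1, tolerance = 1e-9)
  expect_equal(range(sq$polygon[, 1]), c(0, 1), tolerance = 1e-9)
  expect_gt(polygon_signed_area(sq$polygon), 0)  # counterclockwise

  expect_error(slice_cross_section(cube, -0.5), class = "tibtunnel_error_empty_slice")
  expect_error(slice_cross_section(cube, 2), class = "tibtunnel_error_empty_slice")
})

test_that("mid-shaft slice area matches the closed-form profile area", {
  pl <- default_pipeline()
  z <- -60
  cs <- slice_cross_section(pl$mesh, z)
  gt <- pl$landmarks$cortex_flat_params
  s <- gt$taper + (1 - gt$taper) * (z - gt$z_bottom) / (0 - gt$z_bottom)
  analytic <- pl$landmarks$profile_area * s^2
  expect_lt(abs(abs(polygon_signed_area(cs$polygon)) / analytic - 1), 0.01)
})

test_that("idealized right triangle is its own segmentation", {
  poly <- rbind(c(0, 40), c(-30, 0), c(0, 0))
  seg <- segment_cortex(poly, segmentation_config(min_flat_length = 5))
  expect_equal(seg$am_flat, rbind(c(0, 40), c(-30, 0)), tolerance = 1e-12)
  expect_equal(seg$al_flat, rbind(c(0, 40), c(0, 0)), tolerance = 1e-12)
  # posterior tangent is the support line y = 0
  expect_equal(abs(seg$posterior_tangent$dir[2]), 0, tolerance = 1e-9)
  expect_equal(seg$posterior_tangent$point[2], 0, tolerance = 1e-9)

  tri <- approach_triangle(seg)
  expect_equal(tri$angle_al_post_deg, 90, tolerance = 1e-6)
  expect_equal(tri$vertex_apex, c(0, 40), tolerance = 1e-6)
})

test_that("segmentation is equivariant under in-plane rotation", {
  poly <- rbind(c(0, 40), c(-30, 0), c(0, 0))
  theta <- 17 * pi / 180
  seg0 <- segment_cortex(poly)
  segr <- segment_cortex(rotate2d(poly, theta))
  expect_equal(segr$am_flat, rotate2d(seg0$am_flat, theta), tolerance = 1e-9)
  expect_equal(segr$al_flat, rotate2d(seg0$al_flat, theta), tolerance = 1e-9)
})

test_that("synthetic tibia slices recover the ground-truth flat directions", {
  pl <- default_pipeline()
  gt <- pl$landmarks$cortex_flat_params
  for (z in c(-40, -60, -80)) {
    seg <- segment_cortex(slice_cross_section(pl$mesh, z))
    ang <- function(d, d_true) {
      acos(min(1, abs(sum(d * d_true)))) * 180 / pi
    }
    expect_lt(ang(seg$am_dir_fit, gt$am$dir), 1)
    expect_lt(ang(seg$al_dir_fit, gt$al$dir), 1)
  }
})

test_that("entry points interpolate the flats as specified", {
  seg <- toy_triangle_segmentation()
  ep <- locate_entry_points(seg)
  expect_equal(ep["T1", ], c(-10, 40 - 40 / 3), tolerance = 1e-9)
  expect_equal(ep["T2", ], c(-15, 20), tolerance = 1e-9)
  expect_equal(ep["T3", ], c(0, 40), tolerance = 1e-9)  # degenerate crest = apex
  expect_equal(ep["T4", ], c(0, 40 - 40 / 3), tolerance = 1e-9)
  expect_equal(ep["T5", ], c(0, 20), tolerance = 1e-9)

  # mirror-symmetric outline: T1/T4 and T2/T5 mirror about the axis
  sym <- cortex_segmentation(
    am_flat = rbind(c(0, 40), c(25, 0)),
    al_flat = rbind(c(0, 40), c(-25, 0))
  )
  eps <- locate_entry_points(sym)
  expect_equal(unname(eps["T1", 1]), unname(-eps["T4", 1]), tolerance = 1e-9)
  expect_equal(unname(eps["T1", 2]), unname(eps["T4", 2]), tolerance = 1e-9)
  expect_equal(unname(eps["T2", 1]), unname(-eps["T5", 1]), tolerance = 1e-9)

  expect_error(cortex_segmentation(am_flat = rbind(c(0, 0), c(0, 0)),
                                   al_flat = rbind(c(0, 40), c(0, 0))),
               class = "tibtunnel_error_degenerate")
})

test_that("entry points lie on the cross-section polygon", {
  pl <- default_pipeline()
  cs <- slice_cross_section(pl$mesh, -55)
  ep <- locate_entry_points(segment_cortex(cs))
  poly_closed <- rbind(cs$polygon, cs$polygon[1, ])
  expect_lt(max(point_polyline_distance(ep, poly_closed)), 0.1)
})

test_that("tracks are ordered, on-surface, and respect extrusion symmetry", {
  pl <- default_pipeline()
  tracks <- pl$tracks
  # circumferential order T2-T1-T3-T4-T5 from medial to lateral at every level
  for (lev in c(1, 30, 60)) {
    xs <- vapply(tracks, function(t) t$pts[lev, 1], 1)
    expect_true(all(diff(xs[c("T2", "T1", "T3", "T4", "T5")]) < 0))
  }
  # T3 (crest) is the most anterior track everywhere
  for (lev in c(1, 30, 60)) {
    ys <- vapply(tracks, function(t) t$pts[lev, 2], 1)
    expect_equal(names(which.max(ys)), "T3")
  }
  # z strictly decreasing
  for (t in tracks) expect_true(all(diff(t$pts[, 3]) < 0))

  # prism (no taper): tracks are vertical lines
  # entry positions on an untapered prism are vertical up to the endpoint
  # wobble of the discrete flats, bounded by the flatness tolerance
  prism <- generate_subject(subject_params(shape = shape_params(distal_taper = 1)))
  ptracks <- build_entry_tracks(prism$mesh, c(-40, -70), slice_step = 2)
  for (t in ptracks) {
    expect_lt(max(abs(sweep(t$pts[, 1:2, drop = FALSE], 2,
                            t$pts[1, 1:2]))), 0.25)
  }

  # halving the slice step leaves shared levels unchanged
  t1 <- build_entry_tracks(pl$mesh, c(-40, -50), slice_step = 2)
  t2 <- build_entry_tracks(pl$mesh, c(-40, -50), slice_step = 1)
  shared <- match(t1$T1$pts[, 3], t2$T1$pts[, 3])
  expect_lt(max(abs(t1$T1$pts - t2$T1$pts[shared, ])), 1e-9)
})

test_that("cross-section pipeline is rigid-motion equivariant", {
  pl <- default_pipeline()
  cs <- slice_cross_section(pl$mesh, -50)
  # translate in-plane + rotate about z: slicing commutes with the motion
  theta <- 23 * pi / 180
  R <- rotation_matrix(c(0, 0, 1), theta)
  mesh_r <- mesh_transform(pl$mesh, R, c(5, -3, 0))
  cs_r <- slice_cross_section(mesh_r, -50)
  poly_expect <- rotate2d(cs$polygon, theta)
  poly_expect <- sweep(poly_expect, 2, c(-5, 3))
  # same vertex set up to cyclic order: compare via polyline distance
  expect_lt(max(point_polyline_distance(cs_r$polygon,
                                        rbind(poly_expect, poly_expect[1, ]))), 1e-6)
  seg_r <- segment_cortex(cs_r)
  seg0 <- segment_cortex(cs)
  expect_equal(abs(sum(seg_r$am_dir_fit * as.vector(rotate2d(matrix(seg0$am_dir_fit, 1), theta)))),
               1, tolerance = 1e-6)
})

test_that("approach triangle has its right angle at the anterolateral vertex", {
  pl <- default_pipeline()
  seg <- segment_cortex(slice_cross_section(pl$mesh, -60))
  tri <- approach_triangle(seg)
  expect_equal(tri$right_angle_at, "vertex_al_post")
  expect_equal(tri$angle_al_post_deg, 90, tolerance = 0.5)

  # with an exactly perpendicular anterolateral cortex
  perp <- generate_subject(subject_params(shape = shape_params(al_cortex_angle = 90,
                                                            ap_depth = 50)))
  segp <- segment_cortex(slice_cross_section(perp$mesh, -60))
  trip <- approach_triangle(segp)
  expect_equal(trip$angle_al_post_deg, 90, tolerance = 0.5)
})
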