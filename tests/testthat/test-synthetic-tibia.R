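test_that("generation is deterministic and scales exactly", {
  sp <- subject_params(seed = 3L)
  a <- generate_subject(sp)
  b <- generate_subject(sp)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$faces, b$mesh$faces)

  sp2 <- subject_params(global_scale = 2)
  c2 <- generate_subject(sp2)
  base <- generate_subject(subject_params(global_scale = 1))
  expect_identical(c2$mesh$vertices, base$mesh$vertices * 2)
  expect_identical(c2$landmarks$pcl_attachment_center,
                   base$landmarks$pcl_attachment_center * 2)
  expect_identical(c2$landmarks$true_plane_M_normal,
                   base$landmarks$true_plane_M_normal)
})

test_that("default mesh is watertight, outward-oriented, with consistent landmarks", {
  pl <- default_pipeline()
  expect_true(isTRUE(mesh_is_watertight(pl$mesh)))
  expect_gt(mesh_volume(pl$mesh), 0)
  # attachment centre lies on the surface: it is interpolated along a mesh
  # edge, so its distance to the nearest edge of the surrounding faces is zero
  b <- pl$exit_B
  d2 <- rowSums(sweep(mesh_face_centroids(pl$mesh), 2, b)^2)
  near_faces <- pl$mesh$faces[order(d2)[1:20], , drop = FALSE]
  edge_d <- Inf
  for (r in seq_len(nrow(near_faces))) {
    tri <- pl$mesh$vertices[near_faces[r, ], ]
    edge_d <- min(edge_d, point_polyline_distance(matrix(b, 1), rbind(tri, tri[1, ])))
  }
  expect_lt(edge_d, 1e-9)
  expect_equal(sqrt(sum(pl$landmarks$true_plane_M_normal^2)), 1, tolerance = 1e-12)
  # rim curve is on the mesh surface
  expect_true(all(pl$landmarks$plateau_rim_curve[, 1] > 0))
})

test_that("invalid shape parameters are rejected with informative errors", {
  expect_error(shape_params(am_cortex_angle = 85, al_cortex_angle = 80),
               "am_cortex_angle", class = "tibtunnel_error_params")
  expect_error(shape_params(attachment_depth = 20, attachment_facet_height = 15),
               "attachment_depth", class = "tibtunnel_error_params")
  expect_error(shape_params(posterior_width = -1), "posterior_width",
               class = "tibtunnel_error_params")
  expect_error(generate_subject(shape_params(ap_depth = 10)), "ap_depth",
               class = "tibtunnel_error_params")
})

test_that("watertightness holds across random shape draws", {
  # many draws at reduced mesh resolution (validity is resolution-independent),
  # then a handful at the default resolution
  res_small <- mesh_resolution(n_flat = 5, n_crest = 5, n_post = 12,
                               n_levels_top = 6, n_levels_shaft = 5)
  cfg <- population_config()
  subjects <- sample_cohort(1000, seed = 99, config = cfg)
  for (sp in subjects) {
    m <- generate_subject(sp, resolution = res_small)$mesh
    expect_true(isTRUE(mesh_is_watertight(m)))
  }
  for (sp in subjects[1:8]) {
    m <- generate_subject(sp)$mesh
    expect_true(isTRUE(mesh_is_watertight(m)))
    expect_gt(mesh_volume(m), 0)
  }
})

test_that("cohort sampling is reproducible and honors the population spec", {
  a <- sample_cohort(90, seed = 5)
  b <- sample_cohort(90, seed = 5)
  expect_identical(a, b)
  expect_length(a, 90)

  all_female <- sample_cohort(40, seed = 5,
                              config = population_config(male_fraction = 0))
  expect_true(all(vapply(all_female, function(s) s$sex, "") == "female"))

  # sex-conditional height offset recovered within 2 standard errors
  cfg <- population_config()
  big <- sample_cohort(500, seed = 17, config = cfg)
  h <- vapply(big, function(s) s$height, 1)
  sex <- vapply(big, function(s) s$sex, "")
  diff_obs <- mean(h[sex == "male"]) - mean(h[sex == "female"])
  diff_true <- cfg$height_mean[["male"]] - cfg$height_mean[["female"]]
  se <- sqrt(var(h[sex == "male"]) / sum(sex == "male") +
             var(h[sex == "female"]) / sum(sex == "female"))
  expect_lt(abs(diff_obs - diff_true), 2 * se)
  # heights map to scales affinely
  gsc <- vapply(big, function(s) s$global_scale, 1)
  expect_equal(gsc, cfg$scale_intercept + cfg$scale_slope * h, tolerance = 1e-12)

  expect_error(sample_cohort(0, seed = 1), class = "tibtunnel_error_params")
  expect_error(sample_cohort(3, seed = 1, config = list()),
               class = "tibtunnel_error_params")
})
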