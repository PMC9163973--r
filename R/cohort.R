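#' Pipeline run configuration
#'
#' Collects every tolerance and parameter of the end-to-end cohort run. The
#' configuration round-trips through YAML ([save_run_config()] /
#' [load_run_config()]).
#'
#' @param n number of subjects.
#' @param seed RNG seed for the cohort sampler.
#' @param population a [population_config()].
#' @param tunnel_radius tunnel radius in mm (the classical 5 mm drill).
#' @param track_z z range of the entry tracks (mm, proximal then distal).
#' @param slice_step axial slice spacing for track construction (mm).
#' @param flatness_tol chord-deviation tolerance of the cortical flats (mm).
#' @param clearance_tol tangency tolerance of the solver (mm).
#' @param bisection_tol entry-position bisection tolerance (mm).
#' @param scan_step coarse solver scan step along the track (mm).
#' @param exclusion_margin added to the tunnel radius for the aperture
#'   exclusion ball (mm).
#' @param sample_density posterior cortex sample density (points per mm^2).
#' @param out_dir optional output directory for CSV artifacts.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(n = 30, seed = 1L, population = population_config(),
                       tunnel_radius = 5, track_z = c(-22, -95),
                       slice_step = 1, flatness_tol = 0.25,
                       clearance_tol = 0.05, bisection_tol = 0.01,
                       scan_step = 2, exclusion_margin = 1, sample_density = 4,
                       out_dir = NULL) {
  tol_fields <- c(slice_step = slice_step, flatness_tol = flatness_tol,
                  clearance_tol = clearance_tol, bisection_tol = bisection_tol,
                  sample_density = sample_density, tunnel_radius = tunnel_radius)
  if (any(tol_fields <= 0)) {
    abort("all tolerances and step sizes must be > 0", class = "tibtunnel_error_params")
  }
  structure(list(n = as.integer(n), seed = as.integer(seed), population = population,
                 tunnel_radius = tunnel_radius, track_z = track_z,
                 slice_step = slice_step, flatness_tol = flatness_tol,
                 clearance_tol = clearance_tol, bisection_tol = bisection_tol,
                 scan_step = scan_step, exclusion_margin = exclusion_margin,
                 sample_density = sample_density, out_dir = out_dir),
            class = "run_config")
}

#' @param config a [run_config()].
#' @param path YAML file path.
#' @rdname run_config
#' @export
save_run_config <- function(config, path) {
  x <- unclass(config)
  x$population <- unclass(x$population)
  x$population$base_shape <- unclass(x$population$base_shape)
  x$population$height_mean <- as.list(x$population$height_mean)
  x$population$height_sd <- as.list(x$population$height_sd)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  pop <- x$population
  cfg <- run_config(
    n = x$n, seed = x$seed,
    population = population_config(
      male_fraction = pop$male_fraction,
      age_range = unlist(pop$age_range),
      height_mean = unlist(pop$height_mean),
      height_sd = unlist(pop$height_sd),
      scale_intercept = pop$scale_intercept, scale_slope = pop$scale_slope,
      shape_cv = pop$shape_cv,
      base_shape = do.call(shape_params, pop$base_shape)
    ),
    tunnel_radius = x$tunnel_radius, track_z = unlist(x$track_z),
    slice_step = x$slice_step, flatness_tol = x$flatness_tol,
    clearance_tol = x$clearance_tol, bisection_tol = x$bisection_tol,
    scan_step = x$scan_step %||% 2,
    exclusion_margin = x$exclusion_margin, sample_density = x$sample_density,
    out_dir = x$out_dir
  )
  cfg
}

#' Measure all five approaches on one subject
#'
#' Runs the full geometric pipeline for a single subject: plateau plane from
#' the extracted medial rim, entry tracks from sliced cross-sections,
#' posterior cortex sampling, and the maximal-angle solve for each approach.
#'
#' @param subject a [subject_params()] object, or a list with elements `mesh`
#'   and `landmarks` (at least `pcl_attachment_center`) for externally
#'   supplied geometry.
#' @param config a [run_config()].
#' @param isolate_approaches when `TRUE`, a failed approach (e.g. an
#'   infeasible track) is reported as an NA row with a warning instead of
#'   failing the whole subject.
#' @return tibble with one row per approach (columns of [measure_tunnel()]).
#' @export
measure_subject <- function(subject, config = run_config(),
                            isolate_approaches = FALSE) {
  if (inherits(subject, "subject_params")) {
    sid <- subject$subject_id
    geo <- generate_subject(subject)
  } else {
    geo <- subject
    sid <- geo$subject_id %||% "external"
  }
  mesh <- geo$mesh
  exit_b <- geo$landmarks$pcl_attachment_center
  plane_m <- fit_plane_M(extract_medial_rim(mesh))
  seg_cfg <- segmentation_config(flatness_tol = config$flatness_tol)
  tracks <- build_entry_tracks(mesh, config$track_z * (geo$landmarks$global_scale %||% 1),
                               slice_step = config$slice_step, config = seg_cfg)
  samples <- posterior_cortex_samples(
    mesh, exit_b, radius = config$tunnel_radius,
    exclusion_radius = config$tunnel_radius + config$exclusion_margin,
    plane_M = plane_m, density = config$sample_density
  )
  solve_one <- function(tr) {
    spec <- tunnel_spec(exit_b, tr, radius = config$tunnel_radius,
                        clearance_tol = config$clearance_tol)
    tun <- solve_max_angle_tunnel(mesh, spec, plane_m, samples = samples,
                                  scan_step = config$scan_step %||% 2,
                                  z_tol = config$bisection_tol)
    measure_tunnel(tun, plane_m, subject_id = sid)
  }
  if (isolate_approaches) {
    purrr::map_dfr(tracks, function(tr) {
      tryCatch(solve_one(tr), error = function(e) {
        warn(sprintf("approach %s of subject %s failed: %s",
                     tr$approach, sid, conditionMessage(e)))
        tibble(subject_id = sid, approach = tr$approach, psa_deg = NA_real_,
               tth_mm = NA_real_, ttd_mm = NA_real_, clearance_mm = NA_real_,
               converged = FALSE)
      })
    })
  } else {
    purrr::map_dfr(tracks, solve_one)
  }
}

#' Scale a run configuration isotropically
#'
#' Multiplies every length in the configuration (radius, track range, steps,
#' tolerances, exclusion margin) by `s` and divides the area density by
#' `s^2`, so that a subject scaled by `global_scale = s` measured under the
#' scaled configuration is an exact scaled replica of the unit-scale problem:
#' PSA is unchanged and TTH/TTD scale by `s` to floating-point accuracy.
#'
#' @param config a [run_config()].
#' @param s isotropic scale factor.
#' @return the scaled `run_config`.
#' @export
scale_run_config <- function(config, s) {
  config$tunnel_radius <- config$tunnel_radius * s
  config$slice_step <- config$slice_step * s
  config$flatness_tol <- config$flatness_tol * s
  config$clearance_tol <- config$clearance_tol * s
  config$bisection_tol <- config$bisection_tol * s
  config$scan_step <- (config$scan_step %||% 2) * s
  config$exclusion_margin <- config$exclusion_margin * s
  config$sample_density <- config$sample_density / s^2
  config
}

#' Run a full synthetic cohort
#'
#' Samples `n` subjects from the population, measures PSA/TTH/TTD for each
#' approach on every subject, and joins the demographic covariates. A failed
#' subject (e.g. an infeasible track) is logged with a warning and skipped;
#' the run aborts only if more than half the cohort fails.
#'
#' @param config a [run_config()]; `config$out_dir`, when set, receives
#'   `measurements.csv` plus the subgroup tables.
#' @return a `cohort_table` tibble: `subject_id`, `approach`, `psa_deg`,
#'   `tth_mm`, `ttd_mm`, `clearance_mm`, `converged`, `sex`, `age`, `height`,
#'   `global_scale`.
#' @export
#' @examples
#' \donttest{
#' tab <- run_cohort(run_config(n = 2, seed = 42))
#' dplyr::count(tab, approach)
#' }
run_cohort <- function(config = run_config()) {
  subjects <- sample_cohort(config$n, seed = config$seed,
                            config = config$population)
  rows <- vector("list", length(subjects))
  failures <- character(0)
  for (i in seq_along(subjects)) {
    sp <- subjects[[i]]
    rec <- tryCatch(measure_subject(sp, config, isolate_approaches = TRUE),
                    error = function(e) {
      warn(sprintf("subject %s failed and was skipped: %s",
                   sp$subject_id, conditionMessage(e)))
      NULL
    })
    if (is.null(rec)) {
      failures <- c(failures, sp$subject_id)
      next
    }
    rec$sex <- sp$sex; rec$age <- sp$age; rec$height <- sp$height
    rec$global_scale <- sp$global_scale
    rows[[i]] <- rec
  }
  if (length(failures) > length(subjects) / 2) {
    abort(sprintf("more than half the cohort failed (%d of %d): %s",
                  length(failures), length(subjects),
                  paste(failures, collapse = ", ")),
          class = "tibtunnel_error_cohort")
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cohort_table", class(out))
  attr(out, "failures") <- failures
  attr(out, "config") <- config
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(config$out_dir, "measurements.csv"),
                     row.names = FALSE)
    run_subgroup_analysis(out, out_dir = config$out_dir)
  }
  out
}

#' @export
tidy.cohort_table <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(x), .data$approach),
    n = dplyr::n(),
    psa_mean = mean(.data$psa_deg), psa_sd = sd(.data$psa_deg),
    tth_mean = mean(.data$tth_mm), tth_sd = sd(.data$tth_mm),
    ttd_mean = mean(.data$ttd_mm), ttd_sd = sd(.data$ttd_mm),
    .groups = "drop"
  )
}

#' @export
glance.cohort_table <- function(x, ...) {
  an <- one_way_anova(split(x$psa_deg, x$approach))
  tibble(n_subjects = length(unique(x$subject_id)),
         n_measurements = nrow(x),
         n_failures = length(attr(x, "failures") %||% character(0)),
         psa_anova_F = an$statistic, psa_anova_p = an$p_value)
}

#' Plot cohort measurements by approach
#'
#' Bar-and-error summary of PSA, TTH and TTD per approach, annotated with the
#' compact letter display (bars sharing a letter are not significantly
#' different under Tukey HSD).
#'
#' @param object a `cohort_table`.
#' @param parameter which measurement to plot.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cohort_table <- function(object, parameter = c("psa_deg", "tth_mm", "ttd_mm"),
                                  ...) {
  parameter <- match.arg(parameter)
  lab <- c(psa_deg = "PSA (degrees)", tth_mm = "TTH (mm)", ttd_mm = "TTD (mm)")[[parameter]]
  groups <- split(object[[parameter]], object$approach)
  lt <- letter_groups(tukey_pairwise_p(groups))
  d <- tibble(approach = names(groups),
              mean = vapply(groups, mean, 1), sd = vapply(groups, sd, 1),
              letters = as.character(lt))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$approach, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd), width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(y = .data$mean + .data$sd + 2,
                                    label = .data$letters)) +
    ggplot2::labs(x = "tunnel approach", y = lab) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
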