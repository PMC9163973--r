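#' Shape parameters of the parametric proximal tibia
#'
#' Encodes the cross-sectional and longitudinal geometry of the synthetic
#' proximal tibia. The axial cross-section follows the classical description of
#' the proximal tibial shaft: an oblique anteromedial cortical flat, an
#' anterolateral flat nearly perpendicular to the posterior margin, a rounded
#' tibial crest joining them, and a shallow posterior arc. The plateau is a
#' posteriorly sloped cap; the PCL attachment sits on a retro-plateau facet
#' above the convex posterior metaphyseal flare, below which the straight
#' posterior cortex begins.
#'
#' @param shaft_length length of the modelled shaft segment (mm).
#' @param posterior_width medial-lateral extent of the posterior cortex tangent
#'   line (mm) - the base of the cross-sectional triangle.
#' @param am_cortex_angle obliquity of the anteromedial flat to the posterior
#'   tangent (degrees).
#' @param al_cortex_angle angle of the anterolateral flat to the posterior
#'   tangent (degrees); near 90 in normal anatomy.
#' @param crest_radius rounding radius of the tibial crest (mm).
#' @param ap_depth distance from the crest to the posterior cortex (mm).
#' @param plateau_posterior_slope posterior inclination of the plateau plane
#'   (degrees).
#' @param attachment_depth distance of the PCL attachment centre below the
#'   posterior plateau rim (mm).
#' @param attachment_facet_height vertical extent of the retro-plateau facet
#'   above the start of the straight posterior cortex (mm); must exceed
#'   `attachment_depth`, and the difference is the free height below the
#'   attachment that limits tunnel inclination.
#' @param attachment_ml_offset medial(-lateral if negative) offset of the PCL
#'   attachment centre from the posterior midline (mm). The attachment sits
#'   slightly lateral in normal anatomy.
#' @param flare_depth posterior bulge of the metaphyseal flare below the
#'   attachment (mm).
#' @param condyle_depth posterior bulge of the condylar prominences flanking
#'   the attachment fossa (mm).
#' @param condyle_drop extra distal extent of the condylar prominences below
#'   the fossa corner before they blend into the straight cortex (mm).
#' @param facet_inset anterior recession of the facet at the posterior plateau
#'   rim (mm).
#' @param distal_taper isotropic scale of the cross-section at the distal end
#'   of the shaft relative to the plateau level; 1 gives a prism.
#' @return an object of class `shape_params` (a validated named list).
#' @export
#' @examples
#' sp <- shape_params()
#' sp$posterior_width
shape_params <- function(shaft_length = 130,
                         posterior_width = 70,
                         am_cortex_angle = 38,
                         al_cortex_angle = 84,
                         crest_radius = 7,
                         ap_depth = 46,
                         plateau_posterior_slope = 7,
                         attachment_depth = 7,
                         attachment_facet_height = 15.5,
                         attachment_ml_offset = 9,
                         flare_depth = 6,
                         condyle_depth = 5.5,
                         condyle_drop = 7,
                         facet_inset = 5,
                         distal_taper = 0.85) {
  p <- list(
    shaft_length = shaft_length, posterior_width = posterior_width,
    am_cortex_angle = am_cortex_angle, al_cortex_angle = al_cortex_angle,
    crest_radius = crest_radius, ap_depth = ap_depth,
    plateau_posterior_slope = plateau_posterior_slope,
    attachment_depth = attachment_depth,
    attachment_facet_height = attachment_facet_height,
    attachment_ml_offset = attachment_ml_offset,
    flare_depth = flare_depth, condyle_depth = condyle_depth,
    condyle_drop = condyle_drop,
    facet_inset = facet_inset,
    distal_taper = distal_taper
  )
  class(p) <- "shape_params"
  validate_shape_params(p)
  p
}

validate_shape_params <- function(p) {
  chk <- function(ok, msg) {
    if (!isTRUE(ok)) abort(paste0("invalid shape parameters: ", msg),
                           class = "tibtunnel_error_params")
  }
  lengths_pos <- c("shaft_length", "posterior_width", "crest_radius", "ap_depth",
                   "attachment_depth", "attachment_facet_height", "flare_depth",
                   "condyle_depth", "condyle_drop", "facet_inset")
  for (f in lengths_pos) {
    chk(is.numeric(p[[f]]) && length(p[[f]]) == 1 && is.finite(p[[f]]) && p[[f]] > 0,
        paste0(f, " must be a positive finite number"))
  }
  chk(p$am_cortex_angle > 0, "am_cortex_angle must be > 0")
  chk(p$am_cortex_angle < p$al_cortex_angle,
      "am_cortex_angle must be smaller than al_cortex_angle")
  chk(p$al_cortex_angle <= 90, "al_cortex_angle must be <= 90")
  chk(p$attachment_depth < p$attachment_facet_height,
      "attachment_depth must be smaller than attachment_facet_height")
  chk(p$attachment_facet_height < p$shaft_length,
      "attachment_facet_height must be smaller than shaft_length")
  chk(p$distal_taper > 0 && p$distal_taper <= 1.2,
      "distal_taper must be in (0, 1.2]")
  chk(abs(p$plateau_posterior_slope) < 30,
      "plateau_posterior_slope must be below 30 degrees")
  invisible(p)
}

#' @export
print.shape_params <- function(x, ...) {
  cat("<shape_params>\n")
  for (f in names(x)) cat(sprintf("  %-24s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Subject-level parameters for the synthetic generator
#'
#' Bundles the demographic covariates used by the cohort statistics layer with
#' the geometric shape parameters and the overall size factor.
#'
#' @param subject_id character identifier.
#' @param sex `"male"` or `"female"`.
#' @param age age in years.
#' @param height stature in metres.
#' @param global_scale isotropic size factor (dimensionless); typically derived
#'   from height via the affine map in the population config.
#' @param shape a [shape_params()] object.
#' @param seed integer seed recorded with the subject (the generator itself is
#'   deterministic given `shape`; the seed documents the draw that produced it).
#' @return an object of class `subject_params`.
#' @export
subject_params <- function(subject_id = "S001", sex = c("male", "female"),
                           age = 35, height = 1.66, global_scale = 1,
                           shape = shape_params(), seed = 1L) {
  sex <- match.arg(sex)
  if (!is.numeric(height) || height <= 0) {
    abort("invalid subject parameters: height must be > 0", class = "tibtunnel_error_params")
  }
  if (!is.numeric(global_scale) || global_scale <= 0) {
    abort("invalid subject parameters: global_scale must be > 0", class = "tibtunnel_error_params")
  }
  if (!inherits(shape, "shape_params")) shape <- do.call(shape_params, shape)
  structure(list(subject_id = as.character(subject_id), sex = sex, age = age,
                 height = height, global_scale = global_scale, shape = shape,
                 seed = as.integer(seed)),
            class = "subject_params")
}

#' Population distribution specification for cohort sampling
#'
#' Defines the sampling distributions used by [sample_cohort()]: the sex ratio,
#' the age range, sex-conditional height distributions, the affine
#' height-to-scale map and the coefficient of variation applied to each shape
#' parameter. Defaults reflect the demographics of adult knee-CT cohorts
#' (roughly 38% male, ages 16-60) and are calibrated so that solved tunnel
#' angles fall in the 50-61 degree band typical of 3D simulation studies.
#'
#' @param male_fraction probability that a subject is male.
#' @param age_range inclusive age range sampled uniformly (years).
#' @param height_mean named vector, mean height (m) per sex.
#' @param height_sd named vector, height standard deviation (m) per sex.
#' @param scale_intercept,scale_slope affine height (m) to `global_scale` map:
#'   `scale = scale_intercept + scale_slope * height`.
#' @param shape_cv fractional standard deviation applied to the jittered shape
#'   parameters.
#' @param base_shape the population-mean [shape_params()].
#' @return a named list of class `population_config`.
#' @export
population_config <- function(male_fraction = 34 / 90,
                              age_range = c(16, 60),
                              height_mean = c(male = 1.72, female = 1.60),
                              height_sd = c(male = 0.055, female = 0.050),
                              scale_intercept = 1 - 0.85 * 1.66,
                              scale_slope = 0.85,
                              shape_cv = 0.05,
                              base_shape = shape_params()) {
  if (!is.numeric(male_fraction) || male_fraction < 0 || male_fraction > 1) {
    abort("male_fraction must be in [0, 1]", class = "tibtunnel_error_params")
  }
  if (length(age_range) != 2 || diff(age_range) < 0) {
    abort("age_range must be an increasing pair", class = "tibtunnel_error_params")
  }
  for (nm in c("male", "female")) {
    if (!nm %in% names(height_mean) || !nm %in% names(height_sd)) {
      abort("height_mean/height_sd must be named vectors with male and female entries",
            class = "tibtunnel_error_params")
    }
  }
  if (!inherits(base_shape, "shape_params")) base_shape <- do.call(shape_params, base_shape)
  structure(list(male_fraction = male_fraction, age_range = age_range,
                 height_mean = height_mean, height_sd = height_sd,
                 scale_intercept = scale_intercept, scale_slope = scale_slope,
                 shape_cv = shape_cv, base_shape = base_shape),
            class = "population_config")
}
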