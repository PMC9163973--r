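Package: tibtunnel
Title: Simulation of Safe Tibial Tunnel Angles in Transtibial PCL Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-dimensional simulation of transtibial posterior cruciate
    ligament (PCL) reconstruction on parametric proximal-tibia surface meshes.
    Generates synthetic, watertight tibia models with ground-truth landmarks,
    slices and segments the cortical cross-section to derive the five classical
    tunnel entry tracks (anteromedial, tibial crest, anterolateral), constructs
    the medial tibial plateau reference plane by a best-fit-circle method,
    solves for the maximally inclined 5-mm-radius tunnel that leaves the
    posterior tibial cortex intact, and measures the permissive safe angle
    (PSA), tibial tunnel height (TTH) and depth (TTD). Includes the cohort
    statistics layer used in such studies: one-way ANOVA with compact letter
    display, independent t-tests, intraclass correlation agreement, and
    noncentral-F power/sample-size computation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
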