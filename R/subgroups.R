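#' Subgroup analysis of a cohort measurement table
#'
#' Reproduces the classical reporting layout of simulation cohorts: per
#' parameter (PSA/TTH/TTD) and approach (T1-T5), an independent t test
#' between sexes, one-way ANOVAs across age and height groups with all
#' pairwise comparisons, and the approach-wise summary with ANOVA and compact
#' letter display.
#'
#' @param table cohort tibble with columns `subject_id`, `approach`,
#'   `psa_deg`, `tth_mm`, `ttd_mm`, `sex`, `age`, `height` (one row per
#'   subject and approach), as produced by [run_cohort()].
#' @param age_breaks,age_labels age grouping (defaults: 16-30, 31-45, 46-60).
#' @param height_breaks,height_labels height grouping in metres (defaults:
#'   <1.60, 1.60-1.70, >1.70).
#' @param alpha significance threshold for the letter display.
#' @param out_dir optional directory; when given, writes `table1_sex.csv`,
#'   `table2_age.csv`, `table3_height.csv`, `fig5_summary.csv` and
#'   `report.txt`.
#' @return list of tibbles `fig5_summary`, `table1_sex`, `table2_age`,
#'   `table3_height` (class `subgroup_report`).
#' @export
run_subgroup_analysis <- function(table,
                                  age_breaks = c(16, 30, 45, 60),
                                  age_labels = c("young", "middle", "elderly"),
                                  height_breaks = c(-Inf, 1.60, 1.70, Inf),
                                  height_labels = c("<1.60", "1.60-1.70", ">1.70"),
                                  alpha = 0.05, out_dir = NULL) {
  need <- c("subject_id", "approach", "psa_deg", "tth_mm", "ttd_mm",
            "sex", "age", "height")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    abort(paste("table lacks columns:", paste(missing_cols, collapse = ", ")),
          class = "tibtunnel_error_params")
  }
  if (any(duplicated(table[, c("subject_id", "approach")]))) {
    abort("each subject may contribute at most one row per approach",
          class = "tibtunnel_error_params")
  }
  params <- c(psa_deg = "PSA", tth_mm = "TTH", ttd_mm = "TTD")
  approaches <- sort(unique(table$approach))

  tab <- table
  tab$age_group <- cut(tab$age, breaks = age_breaks, labels = age_labels,
                       include.lowest = TRUE)
  tab$height_group <- cut(tab$height, breaks = height_breaks,
                          labels = height_labels)

  msd <- function(x) sprintf("%.2f ± %.2f", mean(x), sd(x))

  # approach-wise summary with ANOVA + letters per parameter
  fig5 <- purrr::map_dfr(names(params), function(col) {
    by_app <- split(tab[[col]], tab$approach)
    by_app <- by_app[order(names(by_app))]
    ok <- all(lengths(by_app) >= 2) && length(by_app) >= 2
    letters_out <- rep(NA_character_, length(by_app))
    p_omni <- NA_real_; f_omni <- NA_real_
    if (isTRUE(ok)) {
      an <- one_way_anova(by_app)
      p_omni <- an$p_value; f_omni <- an$statistic
      letters_out <- letter_groups(tukey_pairwise_p(by_app), alpha)
    }
    tibble(parameter = params[[col]], approach = names(by_app),
           n = lengths(by_app),
           mean = vapply(by_app, mean, 1), sd = vapply(by_app, sd, 1),
           anova_F = f_omni, anova_p = p_omni, letters = as.character(letters_out))
  })

  # sex table: one row per parameter x approach
  sex_tab <- purrr::map_dfr(names(params), function(col) {
    purrr::map_dfr(approaches, function(a) {
      d <- tab[tab$approach == a, ]
      m <- d[[col]][d$sex == "male"]; f <- d[[col]][d$sex == "female"]
      if (length(m) < 2 || length(f) < 2) {
        warn(sprintf("empty or singleton sex group for %s %s: reported as NA",
                     params[[col]], a))
        return(tibble(parameter = paste(params[[col]], sub("T", "", a)),
                      male = NA_character_, female = NA_character_,
                      t = NA_real_, t_squared = NA_real_, p_value = NA_real_))
      }
      tt <- independent_t_test(m, f)
      tibble(parameter = paste(params[[col]], sub("T", "", a)),
             male = msd(m), female = msd(f),
             t = tt$statistic, t_squared = tt$t_squared, p_value = tt$p_value)
    })
  })

  group_table <- function(gvar) {
    lv <- levels(tab[[gvar]])
    purrr::map_dfr(names(params), function(col) {
      purrr::map_dfr(approaches, function(a) {
        d <- tab[tab$approach == a & !is.na(tab[[gvar]]), ]
        groups <- split(d[[col]], d[[gvar]])[lv]
        names(groups) <- lv
        row <- tibble(parameter = paste(params[[col]], sub("T", "", a)))
        for (g in lv) {
          x <- groups[[g]]
          row[[g]] <- if (is.null(x) || length(x) < 2) NA_character_ else msd(x)
        }
        bad <- vapply(groups, function(x) is.null(x) || length(x) < 2, TRUE)
        if (any(bad) || var(vapply(groups[!bad], mean, 1)) +
              sum(vapply(groups[!bad], var, 1)) == 0) {
          if (any(bad)) warn(sprintf("empty subgroup in %s for %s %s: ANOVA reported as NA",
                                     gvar, params[[col]], a))
          row$anova_F <- NA_real_; row$anova_p <- NA_real_
          for (pp in utils::combn(lv, 2, paste, collapse = " vs ")) row[[pp]] <- NA_real_
          return(row)
        }
        an <- tryCatch(one_way_anova(groups), error = function(e) NULL)
        pw <- tryCatch(tukey_pairwise_p(groups), error = function(e) NULL)
        row$anova_F <- if (is.null(an)) NA_real_ else an$statistic
        row$anova_p <- if (is.null(an)) NA_real_ else an$p_value
        for (ij in utils::combn(seq_along(lv), 2, simplify = FALSE)) {
          nm <- paste(lv[ij[1]], "vs", lv[ij[2]])
          row[[nm]] <- if (is.null(pw)) NA_real_ else pw[ij[1], ij[2]]
        }
        row
      })
    })
  }
  age_tab <- group_table("age_group")
  height_tab <- group_table("height_group")

  out <- structure(list(fig5_summary = fig5, table1_sex = sex_tab,
                        table2_age = age_tab, table3_height = height_tab,
                        alpha = alpha),
                   class = "subgroup_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fig5, file.path(out_dir, "fig5_summary.csv"), row.names = FALSE)
    utils::write.csv(sex_tab, file.path(out_dir, "table1_sex.csv"), row.names = FALSE)
    utils::write.csv(age_tab, file.path(out_dir, "table2_age.csv"), row.names = FALSE)
    utils::write.csv(height_tab, file.path(out_dir, "table3_height.csv"), row.names = FALSE)
    writeLines(utils::capture.output(print(out)), file.path(out_dir, "report.txt"))
  }
  out
}

#' @export
print.subgroup_report <- function(x, ...) {
  cat("Cohort subgroup analysis\n")
  cat("========================\n\n")
  cat("Approach summary (mean ± sd, shared letters not significantly different):\n")
  f5 <- x$fig5_summary
  for (p in unique(f5$parameter)) {
    d <- f5[f5$parameter == p, ]
    cat(sprintf("  %s (ANOVA F = %.2f, p = %.3g):\n", p, d$anova_F[1], d$anova_p[1]))
    for (i in seq_len(nrow(d))) {
      cat(sprintf("    %s  %6.2f ± %5.2f  %s\n", d$approach[i], d$mean[i],
                  d$sd[i], d$letters[i]))
    }
  }
  cat("\nSex comparison rows:", nrow(x$table1_sex),
      "| age-group rows:", nrow(x$table2_age),
      "| height-group rows:", nrow(x$table3_height), "\n")
  invisible(x)
}
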