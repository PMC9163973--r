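#' One-way fixed-effects ANOVA from sums of squares
#'
#' Classical omnibus F test computed directly from between- and within-group
#' sums of squares.
#'
#' @param values named list of numeric vectors (one per group), or a data
#'   frame given with `group`/`value` column names.
#' @param group,value tidy-eval column names when `values` is a data frame.
#' @return a `stat_result` object: `test`, `statistic` (F), `df` (pair),
#'   `p_value`, and per-group summary.
#' @export
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
one_way_anova <- function(values, group = NULL, value = NULL) {
  if (is.data.frame(values)) {
    gq <- rlang::enquo(group); vq <- rlang::enquo(value)
    g <- factor(rlang::eval_tidy(gq, values))
    v <- as.numeric(rlang::eval_tidy(vq, values))
    values <- split(v, g)
  }
  values <- lapply(values, function(x) as.numeric(x[is.finite(x)]))
  k <- length(values)
  n_i <- lengths(values)
  if (k < 2) abort("need at least two groups", class = "tibtunnel_error_stats")
  if (any(n_i < 2)) abort("every group needs n >= 2", class = "tibtunnel_error_stats")
  n <- sum(n_i)
  means <- vapply(values, mean, 1)
  grand <- sum(n_i * means) / n
  ss_between <- sum(n_i * (means - grand)^2)
  ss_within <- sum(vapply(values, function(x) sum((x - mean(x))^2), 1))
  df1 <- k - 1; df2 <- n - k
  if (ss_within <= 0 && ss_between <= 0) {
    f_stat <- 0
  } else if (ss_within <= 0) {
    abort("zero within-group variance: F undefined", class = "tibtunnel_error_stats")
  } else {
    f_stat <- (ss_between / df1) / (ss_within / df2)
  }
  p <- pf(f_stat, df1, df2, lower.tail = FALSE)
  new_stat_result("anova", statistic = f_stat, df = c(df1, df2), p_value = p,
                  extra = list(group_means = means, group_n = n_i,
                               ss_between = ss_between, ss_within = ss_within,
                               ms_within = ss_within / df2))
}

#' Pairwise Tukey HSD p-values
#'
#' Studentized-range p-values for all group pairs, the post-hoc family used
#' for the compact letter display.
#'
#' @inheritParams one_way_anova
#' @return symmetric matrix of adjusted p-values with group dimnames.
#' @export
tukey_pairwise_p <- function(values) {
  res <- one_way_anova(values)
  means <- res$group_means; n_i <- res$group_n
  k <- length(means); df2 <- res$df[2]
  msw <- res$ms_within
  p <- matrix(NA_real_, k, k, dimnames = list(names(means), names(means)))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      se <- sqrt(msw / 2 * (1 / n_i[i] + 1 / n_i[j]))
      q <- abs(means[i] - means[j]) / se
      p[i, j] <- p[j, i] <- ptukey(q, k, df2, lower.tail = FALSE)
    }
  }
  diag(p) <- 1
  p
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb letter assignment: two levels share a letter if and only
#' if their pairwise p-value exceeds `alpha`. With an intransitive
#' significance pattern a perfect assignment may be impossible; the function
#' then returns a minimal covering assignment and flags it.
#'
#' @param pairwise_p symmetric matrix of pairwise p-values (dimnames give the
#'   level labels).
#' @param alpha significance threshold.
#' @return named character vector of letter strings per level, with attribute
#'   `consistent` (FALSE when the pattern was intransitive).
#' @export
#' @examples
#' p <- matrix(c(1, .8, .01, .8, 1, .01, .01, .01, 1), 3, 3,
#'             dimnames = list(c("a1", "a2", "a3"), c("a1", "a2", "a3")))
#' letter_groups(p)
letter_groups <- function(pairwise_p, alpha = 0.05) {
  if (!isTRUE(all.equal(pairwise_p, t(pairwise_p), tolerance = 1e-8))) {
    abort("pairwise p matrix must be symmetric", class = "tibtunnel_error_stats")
  }
  k <- nrow(pairwise_p)
  lv <- rownames(pairwise_p)
  if (is.null(lv)) lv <- paste0("L", seq_len(k))
  nonsig <- pairwise_p > alpha
  diag(nonsig) <- TRUE
  # insert-and-absorb: start with one set of all levels; for each significant
  # pair split every set containing both; absorb duplicated/contained sets
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (nonsig[i, j]) next
      new_sets <- list()
      for (s in sets) {
        if (i %in% s && j %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb sets contained in another
      keep <- rep(TRUE, length(new_sets))
      for (a in seq_along(new_sets)) {
        for (b in seq_along(new_sets)) {
          if (a != b && keep[a] && all(new_sets[[a]] %in% new_sets[[b]]) &&
              (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      sets <- new_sets[keep]
    }
  }
  # verify the iff property: every nonsig pair shares a set
  consistent <- TRUE
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      shared <- any(vapply(sets, function(s) i %in% s && j %in% s, TRUE))
      if (nonsig[i, j] != shared) consistent <- FALSE
    }
  }
  # order sets by their first level for stable letters
  ord <- order(vapply(sets, min, 1L))
  sets <- sets[ord]
  letters_out <- rep("", k)
  for (s_i in seq_along(sets)) {
    for (m in sets[[s_i]]) letters_out[m] <- paste0(letters_out[m], letters[s_i])
  }
  names(letters_out) <- lv
  attr(letters_out, "consistent") <- consistent
  if (!consistent) {
    warn("intransitive significance pattern: letter display is a minimal cover")
  }
  letters_out
}

#' Independent two-sample t test (pooled variance)
#'
#' @param a,b numeric vectors.
#' @return a `stat_result` with `statistic` (t), `t_squared` (the F-style
#'   value printed by some reports), `df`, `p_value`.
#' @export
independent_t_test <- function(a, b) {
  a <- as.numeric(a[is.finite(a)]); b <- as.numeric(b[is.finite(b)])
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) abort("need n >= 2 per group", class = "tibtunnel_error_stats")
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  if (sp2 <= 0) abort("zero pooled variance: t undefined", class = "tibtunnel_error_stats")
  t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  p <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  new_stat_result("t_test", statistic = t_stat, df = df, p_value = p,
                  extra = list(t_squared = t_stat^2,
                               mean_a = mean(a), mean_b = mean(b),
                               sd_a = sd(a), sd_b = sd(b), n_a = n1, n_b = n2))
}

#' Intraclass correlation: two-way random, absolute agreement, single measure
#'
#' ICC(2,1) from the two-way mean squares, with the conventional agreement
#' grade: below 0.40 poor, 0.40-0.75 fair to good, above 0.75 excellent.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns,
#'   complete.
#' @return a `stat_result` with `statistic` (ICC), `grade`, the mean squares,
#'   and the F test of subject variance.
#' @export
icc_agreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (k < 2 || n < 5) abort("need >= 2 raters and >= 5 subjects", class = "tibtunnel_error_stats")
  if (anyNA(ratings)) abort("ratings must be complete", class = "tibtunnel_error_stats")
  if (max(ratings) - min(ratings) < .Machine$double.eps * 100) {
    abort("constant ratings matrix: ICC undefined", class = "tibtunnel_error_stats")
  }
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  grade <- if (icc < 0.40) "poor" else if (icc <= 0.75) "fair to good" else "excellent"
  f_stat <- msr / mse
  p <- pf(f_stat, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  new_stat_result("icc", statistic = icc, df = c(n - 1, (n - 1) * (k - 1)),
                  p_value = p,
                  extra = list(grade = grade, msr = msr, msc = msc, mse = mse,
                               f_subjects = f_stat, n_subjects = n, n_raters = k))
}

#' Noncentral-F power of a one-way fixed-effects ANOVA
#'
#' @param n total sample size.
#' @param k number of groups.
#' @param effect_f Cohen's f effect size; the noncentrality is `f^2 * n`.
#' @param alpha type-I error rate.
#' @return power in `[0, 1]`.
#' @export
anova_power <- function(n, k, effect_f, alpha = 0.05) {
  df1 <- k - 1; df2 <- n - k
  if (df2 < 1) return(0)
  crit <- qf(1 - alpha, df1, df2)
  pf(crit, df1, df2, ncp = effect_f^2 * n, lower.tail = FALSE)
}

#' Minimum ANOVA sample size for a target power
#'
#' Smallest total N whose fixed-effects omnibus one-way F test reaches the
#' target power at effect size `effect_f` (noncentrality `f^2 N`,
#' df = (k-1, N-k)), the G*Power-style computation.
#'
#' @param k number of groups.
#' @param effect_f Cohen's f effect size.
#' @param alpha type-I error rate.
#' @param power target power.
#' @return minimal total N (integer).
#' @export
#' @examples
#' anova_sample_size(k = 5, effect_f = 0.5, alpha = 0.05, power = 0.9)
anova_sample_size <- function(k, effect_f, alpha = 0.05, power = 0.9) {
  if (!(alpha > 0 && alpha < 1) || !(power >= 0 && power < 1)) {
    abort("alpha in (0,1) and power in [0,1) required", class = "tibtunnel_error_stats")
  }
  if (effect_f <= 0) abort("effect_f must be > 0", class = "tibtunnel_error_stats")
  lo <- k + 1
  if (anova_power(lo, k, effect_f, alpha) >= power) return(as.integer(lo))
  hi <- lo
  while (anova_power(hi, k, effect_f, alpha) < power) {
    hi <- hi * 2
    if (hi > 1e6) {
      if (anova_power(1e6, k, effect_f, alpha) < power) {
        abort("target power unreachable within N <= 1e6",
              class = "tibtunnel_error_stats")
      }
      hi <- 1e6
      break
    }
  }
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (anova_power(mid, k, effect_f, alpha) >= power) hi <- mid else lo <- mid
  }
  as.integer(hi)
}

new_stat_result <- function(test, statistic, df, p_value, extra = list()) {
  structure(c(list(test = test, statistic = statistic, df = df,
                   p_value = p_value), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result: %s>  statistic = %.4g, df = %s, p = %.4g\n",
              x$test, x$statistic, paste(x$df, collapse = ", "), x$p_value))
  if (!is.null(x$grade)) cat("  agreement grade:", x$grade, "\n")
  invisible(x)
}

#' @export
tidy.stat_result <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic,
         df1 = x$df[1], df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
         p_value = x$p_value,
         grade = if (!is.null(x$grade)) x$grade else NA_character_)
}

#' @export
glance.stat_result <- function(x, ...) tidy(x)
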