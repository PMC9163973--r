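test_that("ANOVA from sums of squares matches hand computation and stats::aov", {
  res <- one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
  expect_equal(res$statistic, 3.0, tolerance = 1e-12)   # SSB = 6, SSW = 6
  expect_equal(res$df, c(2, 6))

  expect_equal(one_way_anova(list(a = c(2, 2, 2), b = c(2, 2, 2)))$statistic, 0)

  set.seed(21)
  d <- data.frame(g = rep(letters[1:4], times = c(7, 9, 6, 8)),
                  y = rnorm(30, rep(c(0, 1, 0.5, 2), times = c(7, 9, 6, 8))))
  mine <- one_way_anova(split(d$y, d$g))
  ref <- summary(aov(y ~ g, data = d))[[1]]
  expect_equal(mine$statistic, ref[["F value"]][1], tolerance = 1e-9)
  expect_equal(mine$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-9)

  # location invariance and scale equivariance of F
  shifted <- one_way_anova(split(d$y + 100, d$g))
  scaled <- one_way_anova(split(d$y * 3.7, d$g))
  expect_equal(shifted$statistic, mine$statistic, tolerance = 1e-9)
  expect_equal(scaled$statistic, mine$statistic, tolerance = 1e-9)

  # two groups: F equals the square of the pooled t statistic
  tt <- independent_t_test(d$y[d$g == "a"], d$y[d$g == "b"])
  an2 <- one_way_anova(list(d$y[d$g == "a"], d$y[d$g == "b"]))
  expect_equal(an2$statistic, tt$statistic^2, tolerance = 1e-9)

  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), class = "tibtunnel_error_stats")
  expect_error(one_way_anova(list(a = c(1, 2))), class = "tibtunnel_error_stats")
})

test_that("pooled t test matches the direct formula and is antisymmetric", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  tt <- independent_t_test(a, b)
  se <- sqrt(((2 * var(a) + 2 * var(b)) / 4) * (1 / 3 + 1 / 3))
  expect_equal(tt$statistic, (mean(a) - mean(b)) / se, tolerance = 1e-12)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(tt$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tt$p_value, ref$p.value, tolerance = 1e-12)

  sw <- independent_t_test(b, a)
  expect_equal(sw$statistic, -tt$statistic, tolerance = 1e-12)
  expect_equal(sw$p_value, tt$p_value, tolerance = 1e-12)

  same <- independent_t_test(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(independent_t_test(c(1, 1), c(1, 1)), class = "tibtunnel_error_stats")
})

test_that("Tukey pairwise p-values match stats::TukeyHSD", {
  set.seed(8)
  d <- data.frame(g = factor(rep(paste0("T", 1:5), each = 12)),
                  y = rnorm(60, rep(c(58, 61, 56, 52, 50), each = 12), 7))
  mine <- tukey_pairwise_p(split(d$y, d$g))
  ref <- TukeyHSD(aov(y ~ g, data = d))$g
  for (rn in rownames(ref)) {
    pair <- strsplit(rn, "-")[[1]]
    expect_equal(mine[pair[1], pair[2]], ref[rn, "p adj"], tolerance = 1e-6)
  }
})

test_that("letter display matches the classical significance patterns", {
  lv <- paste0("T", 1:5)
  mk <- function(fill) matrix(fill, 5, 5, dimnames = list(lv, lv))

  all_sig <- mk(0.001); diag(all_sig) <- 1
  la <- letter_groups(all_sig)
  expect_equal(as.character(la), letters[1:5])

  none_sig <- mk(0.9)
  expect_true(all(letter_groups(none_sig) == "a"))

  # anteromedial pair and anterolateral pair not separable, crest separate
  p <- mk(0.001); diag(p) <- 1
  p["T1", "T2"] <- p["T2", "T1"] <- 0.4
  p["T4", "T5"] <- p["T5", "T4"] <- 0.3
  lp <- letter_groups(p)
  expect_equal(as.character(lp), c("a", "a", "b", "c", "c"))
  expect_true(attr(lp, "consistent"))

  # overlapping chain: 1~2 and 2~3 non-significant but 1 vs 3 significant;
  # the middle level carries both letters
  q <- matrix(c(1, .5, .01, .5, 1, .5, .01, .5, 1), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  lq <- letter_groups(q)
  expect_true(attr(lq, "consistent"))
  expect_equal(as.character(lq), c("a", "ab", "b"))
  # the significant pair shares no letter
  expect_false(any(strsplit(lq[[1]], "")[[1]] %in% strsplit(lq[[3]], "")[[1]]))
})

test_that("ICC(2,1) grades agreement and matches analytic cases", {
  set.seed(13)
  base <- rnorm(20, 50, 8)
  perfect <- cbind(base, base)
  r <- icc_agreement(perfect)
  expect_equal(r$statistic, 1, tolerance = 1e-9)
  expect_equal(r$grade, "excellent")

  # independent ratings: ICC near zero
  noise <- matrix(rnorm(400), 200, 2)
  r0 <- icc_agreement(noise)
  expect_lt(abs(r0$statistic), 0.1)
  expect_equal(r0$grade, "poor")

  # grade cutoffs as conventionally quoted (0.84 and upward is excellent)
  shrink <- function(target) {
    # two raters = subject effect + noise calibrated near the target ICC
    s2 <- target / (1 - target)
    subj <- rnorm(4000, 0, sqrt(s2))
    m <- cbind(subj + rnorm(4000), subj + rnorm(4000))
    icc_agreement(m)
  }
  r84 <- shrink(0.84)
  expect_gt(r84$statistic, 0.75)
  expect_equal(r84$grade, "excellent")
  expect_equal(shrink(0.55)$grade, "fair to good")

  expect_error(icc_agreement(matrix(1, 10, 2)), class = "tibtunnel_error_stats")
  expect_error(icc_agreement(matrix(rnorm(8), 4, 2)), class = "tibtunnel_error_stats")
})

test_that("ICC(2,1) matches the mean-squares definition on a worked matrix", {
  ratings <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2),
                   c(5, 3, 6, 2, 6, 4), c(8, 2, 8, 6, 9, 7))
  r <- icc_agreement(ratings)
  # independent two-way decomposition via anova on the long layout
  long <- data.frame(y = as.vector(ratings),
                     subj = factor(rep(1:6, 4)), rater = factor(rep(1:4, each = 6)))
  ms <- summary(aov(y ~ subj + rater, data = long))[[1]][["Mean Sq"]]
  icc_ref <- (ms[1] - ms[3]) / (ms[1] + (4 - 1) * ms[3] + 4 * (ms[2] - ms[3]) / 6)
  expect_equal(r$statistic, icc_ref, tolerance = 1e-9)
})

test_that("sample size search matches noncentral-t and simulation oracles", {
  expect_equal(anova_sample_size(4, effect_f = 0.5, power = 0), 5L)

  # k = 2 reduces to the two-sample t problem (Cohen's d = 2f)
  f <- 0.4
  n_f <- anova_sample_size(2, effect_f = f, alpha = 0.05, power = 0.85)
  t_power <- function(n) {
    df <- n - 2
    ncp <- f * sqrt(n)
    crit <- qt(0.975, df)
    pt(crit, df, ncp = ncp, lower.tail = FALSE) + pt(-crit, df, ncp = ncp)
  }
  n_t <- 4
  while (t_power(n_t) < 0.85) n_t <- n_t + 1
  expect_lte(abs(n_f - n_t), 2)

  # Monte-Carlo power at the returned N within 0.02 of the noncentral-F value
  set.seed(77)
  k <- 3; f2 <- 0.5
  n_tot <- anova_sample_size(k, effect_f = f2, alpha = 0.05, power = 0.9)
  n_g <- ceiling(n_tot / k); n_tot_sim <- n_g * k
  delta <- f2 * sqrt(3 / 2)             # means (-d, 0, d) give Cohen's f = f2
  mu <- rep(c(-delta, 0, delta), each = n_g)
  n_sim <- 10000
  y <- matrix(rnorm(n_sim * n_tot_sim, mean = rep(mu, times = n_sim)),
              nrow = n_tot_sim)
  g <- rep(1:k, each = n_g)
  gm <- rowsum(y, g) / n_g
  grand <- colMeans(y)
  ssb <- n_g * colSums((gm - matrix(grand, k, n_sim, byrow = TRUE))^2)
  ssw <- colSums((y - gm[g, ])^2)
  f_stats <- (ssb / (k - 1)) / (ssw / (n_tot_sim - k))
  sim_power <- mean(f_stats > qf(0.95, k - 1, n_tot_sim - k))
  expect_lt(abs(sim_power - anova_power(n_tot_sim, k, f2)), 0.02)

  expect_error(anova_sample_size(3, effect_f = 0), class = "tibtunnel_error_stats")
  expect_error(anova_sample_size(3, effect_f = 1e-4, power = 0.999),
               class = "tibtunnel_error_stats")
})
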