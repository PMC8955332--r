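test_that("Cohen's d follows the RMS-pooled formula exactly", {
  expect_equal(cohens_d(1, 1, 1, 1)$d, 0)
  expect_equal(cohens_d(0, 1, 1, 1)$d, 1)
  expect_equal(cohens_d(0.93, 0.11, 1.33, 0.28)$d,
               0.40 / sqrt((0.11^2 + 0.28^2) / 2), tolerance = 1e-12)
  expect_error(cohens_d(0, 0, 1, 0), class = "sinb_degenerate_error")
  expect_error(cohens_d(0, -1, 1, 1), "non-negative")
  # affine invariance: shift both groups by c, scale both by k > 0
  set.seed(11)
  for (k in 1:50) {
    q <- rnorm(4); q[c(2, 4)] <- abs(q[c(2, 4)]) + 0.1
    shift <- rnorm(1); scale <- rexp(1) + 0.1
    d0 <- cohens_d(q[1], q[2], q[3], q[4])$d
    d1 <- cohens_d(q[1] * scale + shift, q[2] * scale,
                   q[3] * scale + shift, q[4] * scale)$d
    expect_equal(d1, d0, tolerance = 1e-10)
  }
})

test_that("skew/kurtosis z screen uses the small-sample standard errors", {
  x <- c(-3, -1, -0.5, 0, 0, 0.5, 1, 3)  # mirrored: zero skewness
  z <- skew_kurt_z(x)
  expect_equal(z$z_skew, 0, tolerance = 1e-12)
  expect_error(skew_kurt_z(rnorm(7)), "n >= 8")

  set.seed(303)
  zn <- skew_kurt_z(rnorm(500))
  expect_true(zn$pass)
  ze <- skew_kurt_z(rexp(50))
  expect_false(ze$pass)
  expect_gt(abs(ze$z_skew), 1.96)

  # z is the adjusted sample skewness over its small-sample SE at n = 50
  n <- 50
  se1 <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  expect_equal(skew_kurt_z(c(1:49, 100))$z_skew,
               e1071::skewness(c(1:49, 100), type = 2) / se1)
})

test_that("one-way ANOVA matches hand-computed sums of squares and t^2", {
  res <- one_way_anova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
  expect_equal(res$F, 1.5)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 4)
  # identical groups: F = 0
  expect_equal(one_way_anova(c(1, 2, 1, 2), c("a", "a", "b", "b"))$F, 0)
  # zero within-group variance is a degenerate signal, not an infinite F
  expect_error(one_way_anova(c(0, 0, 0, 1, 1, 1), rep(c("a", "b"), each = 3)),
               class = "sinb_degenerate_error")
  expect_error(one_way_anova(1:3, rep("a", 3)), "two groups")
  # F equals the square of the pooled-variance t statistic
  set.seed(21)
  for (k in 1:100) {
    y <- rnorm(sample(8:20, 1))
    g <- sample(c("a", "b"), length(y), replace = TRUE)
    if (min(table(factor(g, levels = c("a", "b")))) < 2) next
    f <- one_way_anova(y, g)$F
    t2 <- t.test(y ~ g, var.equal = TRUE)$statistic^2
    expect_equal(f, unname(t2), tolerance = 1e-10)
  }
})

test_that("the mixed ANOVA matches the stratified sums-of-squares oracle", {
  set.seed(99)
  for (k in 1:30) {
    scores <- random_scores(n1 = sample(4:12, 1), n2 = sample(4:12, 1),
                            effect = runif(1, 0, 1))
    got <- mixed_anova(scores)
    want <- oracle_mixed_anova_222(scores)
    expect_equal(setNames(got$F, got$effect), want[got$effect],
                 tolerance = 1e-10)
    expect_true(all(got$df1 == 1))
    expect_true(all(got$df2 == nrow(scores) - 2))
    for (e in c("right", "left")) {
      got2 <- mixed_anova(scores, within = "scoring", ear = e)
      want2 <- oracle_mixed_anova_22(scores, e)
      expect_equal(setNames(got2$F, got2$effect), want2[got2$effect],
                   tolerance = 1e-10)
    }
  }
})

test_that("with balanced groups the mixed ANOVA agrees with aov error strata", {
  set.seed(7)
  scores <- random_scores(n1 = 8, n2 = 8, effect = 0.8)
  long <- reshape(scores, direction = "long",
                  varying = list(c("snr50_word_right", "snr50_word_left",
                                   "snr50_syll_right", "snr50_syll_left")),
                  v.names = "snr50",
                  times = c("word.right", "word.left", "syll.right",
                            "syll.left"))
  long$scoring <- factor(sub("\\..*", "", long$time))
  long$ear <- factor(sub(".*\\.", "", long$time))
  long$participant_id <- factor(long$participant_id)
  long$group <- factor(long$group)
  fit <- summary(aov(snr50 ~ group * scoring * ear +
                       Error(participant_id / (scoring * ear)), data = long))
  aov_f <- c(
    group = fit[["Error: participant_id"]][[1]]["group", "F value"],
    scoring = fit[["Error: participant_id:scoring"]][[1]]["scoring", "F value"],
    `group:scoring` = fit[["Error: participant_id:scoring"]][[1]][
      "group:scoring", "F value"],
    ear = fit[["Error: participant_id:ear"]][[1]]["ear", "F value"],
    `group:ear` = fit[["Error: participant_id:ear"]][[1]]["group:ear",
                                                          "F value"],
    `scoring:ear` = fit[["Error: participant_id:scoring:ear"]][[1]][
      "scoring:ear", "F value"],
    `group:scoring:ear` = fit[["Error: participant_id:scoring:ear"]][[1]][
      "group:scoring:ear", "F value"]
  )
  got <- mixed_anova(scores)
  expect_equal(setNames(got$F, got$effect), aov_f[got$effect],
               tolerance = 1e-8)
})

test_that("shuffled group labels put the group F near its null distribution", {
  set.seed(13)
  scores <- random_scores(n1 = 15, n2 = 12, effect = 1.5)
  f <- replicate(400, {
    sh <- scores
    sh$group <- sample(sh$group)
    mixed_anova(sh)$F[1]
  })
  df2 <- nrow(scores) - 2
  # null mean of an F(1, df2) variate is df2/(df2 - 2)
  expect_lt(abs(mean(f) - df2 / (df2 - 2)), 0.35)
})

test_that("degenerate and malformed score tables are signalled", {
  scores <- random_scores(n1 = 6, n2 = 6)
  # no within-subject variation at all: within strata collapse
  flat <- scores
  flat$snr50_word_right <- flat$snr50_word_left <-
    flat$snr50_syll_right <- flat$snr50_syll_left <- rep(c(0, 1), 6)
  expect_error(mixed_anova(flat), class = "sinb_degenerate_error")
  one_group <- scores
  one_group$group <- "control"
  expect_error(mixed_anova(one_group), "two groups")
  na_scores <- scores
  na_scores$snr50_word_left[2] <- NA
  expect_error(mixed_anova(na_scores), "complete cases")
})

test_that("cohort effect sizes report d with the moments that produced it", {
  set.seed(55)
  scores <- random_scores(n1 = 10, n2 = 9, effect = 1)
  es <- cohort_effect_sizes(scores)
  expect_equal(nrow(es), 4)
  row <- es[es$measure == "snr50_word_right", ]
  ctrl <- scores$snr50_word_right[scores$group == "control"]
  apd <- scores$snr50_word_right[scores$group == "APD"]
  expect_equal(row$d, (mean(apd) - mean(ctrl)) /
                 sqrt((sd(ctrl)^2 + sd(apd)^2) / 2))
})
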