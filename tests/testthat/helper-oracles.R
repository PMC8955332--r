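# Independent oracles and fixture builders, kept deliberately separate from
# the implementation paths they check.

# Per-level summation form of the Spearman-Karber estimator: accumulates
# level proportions one at a time instead of using the pooled-count formula.
oracle_sk <- function(counts, design, mode) {
  w <- if (mode == "word") design$words_per_level else
    design$words_per_level * design$syllables_per_word
  acc <- 0
  for (j in seq_along(counts)) acc <- acc + counts[j] / w
  design$initial_snr_db + design$step_db / 2 - design$step_db * acc
}

# Build a complete single-ear trial table from a list of per-level syllable
# pairs: outcomes[[level]] is a 2-column 0/1 matrix, one row per word.
build_administration <- function(outcomes, participant_id = "P1",
                                 group = "control", ear = "right",
                                 design = sinb_design()) {
  rows <- lapply(seq_along(outcomes), function(j) {
    m <- outcomes[[j]]
    data.frame(
      participant_id = participant_id, group = group, ear = ear,
      level_index = j - 1L,
      snr_db = level_snrs(design)[j],
      word_id = sprintf("L%d_W%02d", j - 1L, seq_len(nrow(m))),
      syll1_correct = m[, 1L], syll2_correct = m[, 2L],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# n words with both syllables correct, k with exactly one, rest neither.
level_outcomes <- function(n_both, n_one, w = 10L) {
  m <- matrix(0L, w, 2L)
  if (n_both > 0) m[seq_len(n_both), ] <- 1L
  if (n_one > 0) m[n_both + seq_len(n_one), 1L] <- 1L
  m
}

# Random per-participant score table fixture.
random_scores <- function(n1 = 6L, n2 = 5L, effect = 0) {
  n <- n1 + n2
  grp <- rep(c("control", "APD"), c(n1, n2))
  data.frame(
    participant_id = sprintf("S%03d", seq_len(n)),
    group = grp,
    snr50_word_right = rnorm(n) + effect * (grp == "APD"),
    snr50_word_left  = rnorm(n) + effect * (grp == "APD"),
    snr50_syll_right = rnorm(n) - 1 + 0.5 * effect * (grp == "APD"),
    snr50_syll_left  = rnorm(n) - 1 + 0.5 * effect * (grp == "APD"),
    stringsAsFactors = FALSE
  )
}

# Brute-force stratified sums-of-squares mixed ANOVA for the 2-level
# between-group design, built from first principles on per-subject derived
# scores: the between stratum is a one-way ANOVA on subject means; each
# within effect is carried by a per-subject contrast variable, whose
# unweighted grand mean tests the within main effect and whose group
# difference tests the group interaction, both against the contrast's
# pooled residual variance.
oracle_contrast_f <- function(z, group) {
  ng <- tabulate(group)
  zbar <- tapply(z, group, mean)
  mse <- sum((z - ave(z, group))^2) / (length(z) - 2)
  c(main = mean(zbar)^2 / (mse * (1 / ng[1] + 1 / ng[2]) / 4),
    interaction = unname(diff(zbar))^2 / (mse * (1 / ng[1] + 1 / ng[2])))
}

oracle_mixed_anova_222 <- function(scores) {
  group <- factor(scores$group)
  Y <- as.matrix(scores[, c("snr50_word_right", "snr50_word_left",
                            "snr50_syll_right", "snr50_syll_left")])
  m <- rowMeans(Y)
  # contrasts follow the factor codings used by the package (word, syll;
  # right, left) but are computed without any model fit
  z_scoring <- (Y[, 3] + Y[, 4] - Y[, 1] - Y[, 2]) / 4
  z_ear <- (Y[, 2] + Y[, 4] - Y[, 1] - Y[, 3]) / 4
  z_se <- (Y[, 1] - Y[, 2] - Y[, 3] + Y[, 4]) / 4
  ng <- tabulate(group)
  mbar <- tapply(m, group, mean)
  mse_b <- sum((m - ave(m, group))^2) / (length(m) - 2)
  f_group <- unname(diff(mbar))^2 / (mse_b * (1 / ng[1] + 1 / ng[2]))
  fs <- oracle_contrast_f(z_scoring, group)
  fe <- oracle_contrast_f(z_ear, group)
  fse <- oracle_contrast_f(z_se, group)
  c(group = f_group,
    scoring = unname(fs["main"]), `group:scoring` = unname(fs["interaction"]),
    ear = unname(fe["main"]), `group:ear` = unname(fe["interaction"]),
    `scoring:ear` = unname(fse["main"]),
    `group:scoring:ear` = unname(fse["interaction"]))
}

oracle_mixed_anova_22 <- function(scores, ear) {
  group <- factor(scores$group)
  word <- scores[[paste0("snr50_word_", ear)]]
  syll <- scores[[paste0("snr50_syll_", ear)]]
  m <- (word + syll) / 2
  z <- (syll - word) / 2
  ng <- tabulate(group)
  mbar <- tapply(m, group, mean)
  mse_b <- sum((m - ave(m, group))^2) / (length(m) - 2)
  f_group <- unname(diff(mbar))^2 / (mse_b * (1 / ng[1] + 1 / ng[2]))
  fz <- oracle_contrast_f(z, group)
  c(group = f_group, scoring = unname(fz["main"]),
    `group:scoring` = unname(fz["interaction"]))
}
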