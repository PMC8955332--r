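#' @keywords internal
stop_degenerate <- function(...) {
  msg <- paste0(...)
  cond <- structure(
    class = c("sinb_degenerate_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

#' Cohen's d between two groups
#'
#' Standardised mean difference using the root-mean-square of the two group
#' standard deviations: `d = (m2 - m1) / sqrt((sd1^2 + sd2^2) / 2)`. The
#' sign is positive when group 2 (by convention the APD group) has the
#' larger mean. Invariant under shifting both groups by a constant or
#' scaling both by a positive factor.
#'
#' @param m1,sd1 Mean and SD of group 1 (control).
#' @param m2,sd2 Mean and SD of group 2 (APD).
#' @return Data frame with columns `d`, `m1`, `sd1`, `m2`, `sd2`
#'   (vectorised over its arguments).
#' @examples
#' cohens_d(0.93, 0.11, 1.33, 0.28)$d  # 1.880
#' @export
cohens_d <- function(m1, sd1, m2, sd2) {
  if (any(sd1 < 0) || any(sd2 < 0)) {
    stop_validation("standard deviations must be non-negative")
  }
  if (any(sd1 == 0 & sd2 == 0)) {
    stop_degenerate("both group SDs are zero; Cohen's d is undefined")
  }
  data.frame(d = (m2 - m1) / sqrt((sd1^2 + sd2^2) / 2),
             m1 = m1, sd1 = sd1, m2 = m2, sd2 = sd2)
}

#' Skewness/kurtosis z screen for normality
#'
#' Standardises the adjusted sample skewness and excess kurtosis by their
#' small-sample standard errors,
#' `SE(g1) = sqrt(6n(n-1) / ((n-2)(n+1)(n+3)))` and
#' `SE(g2) = 2 SE(g1) sqrt((n^2-1) / ((n-3)(n+5)))`; a sample passes the
#' screen when both z statistics lie within ±1.96.
#'
#' @param x Numeric sample, length at least 8 (the SE expressions are
#'   unstable below that).
#' @return List with `z_skew`, `z_kurt`, `pass`, `n`.
#' @export
skew_kurt_z <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8L) stop_validation("normality screen needs n >= 8, got ", n)
  g1 <- e1071::skewness(x, type = 2)
  g2 <- e1071::kurtosis(x, type = 2)
  se1 <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  se2 <- 2 * se1 * sqrt((n^2 - 1) / ((n - 3) * (n + 5)))
  z1 <- g1 / se1
  z2 <- g2 / se2
  list(z_skew = z1, z_kurt = z2, pass = abs(z1) <= 1.96 && abs(z2) <= 1.96,
       n = n)
}

#' Normality screen for every measure and group
#'
#' Groups smaller than 8 cannot support the small-sample SE formulas; their
#' rows are returned as `NA` with a warning rather than aborting the
#' analysis.
#'
#' @param scores Per-participant score table ([score_trials()] output).
#' @return Data frame with one row per group x measure: `group`, `measure`,
#'   `z_skew`, `z_kurt`, `pass`.
#' @export
normality_screen <- function(scores) {
  measures <- setdiff(score_columns, c("participant_id", "group"))
  rows <- list()
  small <- character(0)
  for (g in unique(scores$group)) {
    for (m in measures) {
      x <- scores[[m]][scores$group == g]
      if (length(x) < 8L) {
        small <- union(small, g)
        z <- list(z_skew = NA_real_, z_kurt = NA_real_, pass = NA)
      } else {
        z <- skew_kurt_z(x)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, measure = m, z_skew = z$z_skew, z_kurt = z$z_kurt,
        pass = z$pass, stringsAsFactors = FALSE
      )
    }
  }
  if (length(small)) {
    warning("normality screen skipped for groups with n < 8: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  do.call(rbind, rows)
}

#' One-way between-groups ANOVA
#'
#' Standard F test for a group difference on one measure, with degrees of
#' freedom (1, n_total - 2) for two groups. Zero within-group variance
#' raises an explicit degenerate-variance error rather than an infinite F.
#'
#' @param values Numeric response vector.
#' @param group Group labels (two levels).
#' @return Data frame row: `effect`, `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop_validation("need at least two groups")
  if (any(tabulate(group) < 2L)) {
    stop_validation("each group needs at least 2 observations")
  }
  fit <- stats::lm(values ~ group)
  ssw <- sum(stats::residuals(fit)^2)
  if (ssw <= 1e-12 * max(1, sum(values^2))) {
    stop_degenerate("zero within-group variance; F is unbounded")
  }
  tab <- stats::anova(fit)
  data.frame(effect = "group", F = tab["group", "F value"],
             df1 = tab["group", "Df"], df2 = tab["Residuals", "Df"],
             p = tab["group", "Pr(>F)"], stringsAsFactors = FALSE)
}

measure_matrix <- function(scores, within, ear) {
  if (setequal(within, c("scoring", "ear"))) {
    cols <- c("snr50_word_right", "snr50_word_left",
              "snr50_syll_right", "snr50_syll_left")
    idata <- data.frame(
      scoring = factor(c("word", "word", "syll", "syll"),
                       levels = c("word", "syll")),
      ear = factor(c("right", "left", "right", "left"),
                   levels = c("right", "left"))
    )
    idesign <- ~ scoring * ear
  } else if (identical(within, "scoring")) {
    cols <- paste0("snr50_", c("word", "syll"), "_", ear)
    idata <- data.frame(scoring = factor(c("word", "syll"),
                                         levels = c("word", "syll")))
    idesign <- ~ scoring
  } else if (identical(within, "ear")) {
    cols <- paste0("snr50_", ear, "_", c("right", "left"))
    idata <- data.frame(ear = factor(c("right", "left"),
                                     levels = c("right", "left")))
    idesign <- ~ ear
  } else {
    stop_validation("`within` must be 'scoring', 'ear' or both")
  }
  list(cols = cols, idata = idata, idesign = idesign)
}

#' Mixed repeated-measures ANOVA on the SinB measures
#'
#' Fits the study's mixed design: `group` between subjects and the chosen
#' within-subject factors (`scoring`, `ear`, or both, each with two
#' levels). The between effect is tested against subjects-within-groups;
#' each within effect and its interaction with group against the
#' corresponding subject-by-factor stratum. Sums of squares are Type
#' III-equivalent (unweighted marginal means, via sum-to-zero contrasts),
#' appropriate for the unbalanced group sizes.
#'
#' @param scores Per-participant score table with complete cases.
#' @param within Character vector, subset of `c("scoring", "ear")`.
#' @param ear When `within = "scoring"`, which ear's measures to analyse
#'   (`"right"` or `"left"`); when `within = "ear"`, which scoring mode
#'   (`"word"` or `"syll"`).
#' @return Data frame with one row per effect: `effect`, `F`, `df1`,
#'   `df2`, `p`. Degenerate error strata (all listeners identical on a
#'   contrast) raise a classed degenerate-variance error.
#' @examples
#' cfg <- sinb_scenario("default")
#' scores <- score_trials(simulate_cohorts(cfg), cfg$design)
#' mixed_anova(scores)                     # omnibus 2 x 2 x 2
#' mixed_anova(scores, "scoring", "left")  # per-ear 2 x 2
#' @export
mixed_anova <- function(scores, within = c("scoring", "ear"), ear = "right") {
  measures <- setdiff(score_columns, c("participant_id", "group"))
  missing_cols <- setdiff(c("group", measures), names(scores))
  if (length(missing_cols)) {
    stop_validation("missing score columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(scores[measures])) {
    stop_validation("score table has missing cells; complete cases required")
  }
  group <- factor(scores$group)
  if (nlevels(group) < 2L) stop_validation("need two groups, got one")
  if (any(tabulate(group) < 2L)) {
    stop_validation("each group needs at least 2 participants")
  }
  mm <- measure_matrix(scores, within, ear)
  Y <- as.matrix(scores[, mm$cols])
  dat <- data.frame(group = group)
  contrasts(dat$group) <- stats::contr.sum(nlevels(group))
  fit <- stats::lm(Y ~ group, data = dat)
  ut <- tryCatch({
    withCallingHandlers({
      av <- car::Anova(fit, idata = mm$idata, idesign = mm$idesign, type = 3)
      summary(av, multivariate = FALSE)$univariate.tests
    }, warning = function(w) {
      # car warns about unavailable sphericity corrections when an error
      # SSP matrix is singular; the degenerate check below covers that case
      if (grepl("SSP|sphericity", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }, error = function(cnd) {
    # a singular fit on validated complete-case input means a collapsed
    # error stratum (e.g. no variation on a within-subject contrast)
    stop_degenerate("degenerate score table, mixed ANOVA undefined: ",
                    conditionMessage(cnd))
  })
  keep <- setdiff(rownames(ut), "(Intercept)")
  err_ss <- ut[keep, "Error SS"]
  scale <- max(1, sum(Y^2))
  if (any(err_ss <= 1e-12 * scale)) {
    bad <- keep[err_ss <= 1e-12 * scale][1L]
    stop_degenerate("degenerate error stratum for effect '", bad,
                    "': no residual variance")
  }
  data.frame(
    effect = keep,
    F = unname(ut[keep, "F value"]),
    df1 = unname(ut[keep, "num Df"]),
    df2 = unname(ut[keep, "den Df"]),
    p = unname(ut[keep, "Pr(>F)"]),
    stringsAsFactors = FALSE
  )
}

#' Group effect sizes for all four measures
#'
#' Cohen's d (APD vs control) for each SNR50 measure, with the group means
#' and SDs it was computed from.
#'
#' @param scores Per-participant score table.
#' @return Data frame with one row per measure: `measure`, `d`, `m1`,
#'   `sd1` (control), `m2`, `sd2` (APD).
#' @export
cohort_effect_sizes <- function(scores) {
  measures <- setdiff(score_columns, c("participant_id", "group"))
  ctrl <- scores[scores$group == "control", , drop = FALSE]
  apd <- scores[scores$group == "APD", , drop = FALSE]
  if (nrow(ctrl) == 0L || nrow(apd) == 0L) {
    stop_validation("need both an APD and a control group")
  }
  rows <- lapply(measures, function(m) {
    cbind(measure = m,
          cohens_d(mean(ctrl[[m]]), stats::sd(ctrl[[m]]),
                   mean(apd[[m]]), stats::sd(apd[[m]])))
  })
  do.call(rbind, rows)
}
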