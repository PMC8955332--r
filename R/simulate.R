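#' Specify a simulated listener cohort
#'
#' A cohort is a group of listeners whose syllable-level psychometric
#' functions are logistic in SNR with a common slope, listener-specific
#' midpoints drawn around a group mean, and a fixed left-ear offset. The
#' two syllables of a word share one success probability and are coupled
#' through a shared-draw mixture (see [draw_word_outcome()]).
#'
#' @param n_participants Number of listeners (at least 2).
#' @param threshold_mean_db Group-mean right-ear psychometric midpoint, dB
#'   SNR. Lower means better performance.
#' @param threshold_sd_db Between-listener SD of the midpoint, dB (one
#'   listener effect shared by both ears).
#' @param slope_db Logistic scale parameter, dB; smaller is steeper.
#' @param within_word_dependence Probability in \[0, 1\] that the two
#'   syllables of a word share a single Bernoulli draw.
#' @param ear_offset_db Additive left-ear midpoint shift relative to the
#'   right ear, dB.
#' @param label Group label used in emitted trial records
#'   (`"control"` or `"APD"`).
#'
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_participants,
                        threshold_mean_db,
                        threshold_sd_db,
                        slope_db,
                        within_word_dependence,
                        ear_offset_db = 0,
                        label = "control") {
  n_participants <- as.integer(n_participants)
  if (is.na(n_participants) || n_participants < 2L) {
    stop_validation("`n_participants` must be at least 2")
  }
  if (!is.finite(slope_db) || slope_db <= 0) {
    stop_validation("`slope_db` must be positive")
  }
  if (!is.finite(threshold_sd_db) || threshold_sd_db < 0) {
    stop_validation("`threshold_sd_db` must be non-negative")
  }
  if (!is.finite(within_word_dependence) ||
      within_word_dependence < 0 || within_word_dependence > 1) {
    stop_validation("`within_word_dependence` must lie in [0, 1]")
  }
  structure(
    list(
      n_participants = n_participants,
      threshold_mean_db = as.numeric(threshold_mean_db),
      threshold_sd_db = as.numeric(threshold_sd_db),
      slope_db = as.numeric(slope_db),
      within_word_dependence = as.numeric(within_word_dependence),
      ear_offset_db = as.numeric(ear_offset_db),
      label = as.character(label)
    ),
    class = "cohort_spec"
  )
}

#' Assemble a two-cohort simulation configuration
#'
#' @param design A [sinb_design()] object.
#' @param control,apd [cohort_spec()] objects for the typically developing
#'   and APD cohorts.
#' @param seed Integer seed; fully determines the simulated trial table.
#'
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(design, control, apd, seed = 1L) {
  stopifnot(inherits(design, "sinb_design"),
            inherits(control, "cohort_spec"),
            inherits(apd, "cohort_spec"))
  seed <- as.integer(seed)
  if (is.na(seed)) stop_validation("`seed` must be an integer")
  structure(list(design = design, control = control, apd = apd, seed = seed),
            class = "simulation_config")
}

#' Logistic syllable psychometric function
#'
#' Probability of correctly repeating a syllable at a given SNR, for a
#' listener with midpoint `threshold_db` and scale `slope_db`:
#' `1 / (1 + exp(-(snr - threshold)/slope))`. The guess rate is zero
#' (open-set repetition against babble).
#'
#' @param snr_db Stimulus SNR, dB (vectorised).
#' @param threshold_db Psychometric midpoint, dB SNR.
#' @param slope_db Logistic scale, dB; must be positive.
#' @return Success probability in (0, 1), strictly increasing in `snr_db`.
#' @export
syllable_success_prob <- function(snr_db, threshold_db, slope_db) {
  if (any(!is.finite(slope_db)) || any(slope_db <= 0)) {
    stop_validation("`slope_db` must be positive")
  }
  stats::plogis((snr_db - threshold_db) / slope_db)
}

#' Draw correlated syllable outcomes for words
#'
#' Each word's two syllables are marginally Bernoulli(`p`) and coupled by a
#' shared-draw mixture: with probability `rho` one draw is copied to both
#' syllables, otherwise they are independent. Hence
#' `P(both correct) = rho * p + (1 - rho) * p^2`.
#'
#' @param p Per-syllable success probability (vectorised over words).
#' @param rho Within-word dependence in \[0, 1\].
#' @return Data frame with 0/1 columns `syll1_correct`, `syll2_correct`,
#'   one row per element of `p`. Consumes the R random number stream.
#' @export
draw_word_outcome <- function(p, rho) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_validation("`p` must lie in [0, 1]")
  }
  if (!is.finite(rho) || rho < 0 || rho > 1) {
    stop_validation("`rho` must lie in [0, 1]")
  }
  n <- length(p)
  share <- stats::runif(n) < rho
  b1 <- stats::runif(n) < p
  b2 <- stats::runif(n) < p
  s2 <- ifelse(share, b1, b2)
  data.frame(syll1_correct = as.integer(b1), syll2_correct = as.integer(s2))
}

#' Simulate one listener's administration
#'
#' Emits a complete single- or two-ear trial table for one listener: every
#' design level gets `words_per_level` words, each word's syllable pair
#' drawn by [draw_word_outcome()] at that level's success probability.
#'
#' @param thresholds Named numeric vector of per-ear psychometric midpoints
#'   (names among `"right"`, `"left"`), dB SNR.
#' @param design A [sinb_design()] object.
#' @param rho Within-word dependence.
#' @param slope_db Logistic scale, dB.
#' @param participant_id,group Identifiers copied into the records.
#' @return Data frame in the trial schema, `n_levels * words_per_level`
#'   rows per ear.
#' @export
simulate_administration <- function(thresholds, design, rho, slope_db,
                                    participant_id = "P1", group = "control") {
  stopifnot(inherits(design, "sinb_design"))
  ears <- names(thresholds)
  if (is.null(ears) || !all(ears %in% c("right", "left"))) {
    stop_validation("`thresholds` must be named with ears 'right'/'left'")
  }
  snr <- level_snrs(design)
  w <- design$words_per_level
  out <- lapply(ears, function(e) {
    lev <- rep(seq_len(design$n_levels) - 1L, each = w)
    p <- syllable_success_prob(rep(snr, each = w), thresholds[[e]], slope_db)
    syl <- draw_word_outcome(p, rho)
    data.frame(
      participant_id = participant_id,
      group = group,
      ear = e,
      level_index = lev,
      snr_db = rep(snr, each = w),
      word_id = sprintf("L%d_W%02d", lev, rep(seq_len(w), design$n_levels)),
      syl,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

simulate_one_cohort <- function(spec, design) {
  n <- spec$n_participants
  eps <- stats::rnorm(n, 0, spec$threshold_sd_db)
  thr <- cbind(
    right = spec$threshold_mean_db + eps,
    left  = spec$threshold_mean_db + spec$ear_offset_db + eps
  )
  L <- design$n_levels
  w <- design$words_per_level
  snr <- level_snrs(design)
  # fully vectorised: one block of n * 2 * L * w words, RNG order fixed
  pid <- sprintf("%s%03d", spec$label, seq_len(n))
  grid <- expand.grid(word = seq_len(w), level = seq_len(L) - 1L,
                      ear = c("right", "left"), participant = seq_len(n),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  thr_row <- thr[cbind(grid$participant, match(grid$ear, colnames(thr)))]
  p <- syllable_success_prob(snr[grid$level + 1L], thr_row, spec$slope_db)
  syl <- draw_word_outcome(p, spec$within_word_dependence)
  data.frame(
    participant_id = pid[grid$participant],
    group = spec$label,
    ear = grid$ear,
    level_index = grid$level,
    snr_db = snr[grid$level + 1L],
    word_id = sprintf("L%d_W%02d", grid$level, grid$word),
    syl,
    stringsAsFactors = FALSE
  )
}

#' Simulate trial tables for both cohorts
#'
#' Draws each listener's midpoint as `Normal(threshold_mean_db, sd^2)` with
#' the cohort's `ear_offset_db` added for the left ear — one listener effect
#' shared across ears, so the two ears of a listener are correlated as a
#' repeated-measures analysis presumes — then simulates complete
#' administrations for every listener. Output is bitwise reproducible for a
#' fixed configuration.
#'
#' @param config A [simulation_config()] object.
#' @return Data frame in the trial schema: control cohort first, then APD.
#' @examples
#' cfg <- sinb_scenario("default")
#' trials <- simulate_cohorts(cfg)
#' nrow(trials)  # 55 listeners x 2 ears x 50 words
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  rbind(
    simulate_one_cohort(config$control, config$design),
    simulate_one_cohort(config$apd, config$design)
  )
}

#' Expected Spearman-Karber scores for a cohort
#'
#' The SK score is linear in the per-level correct counts, so its
#' expectation over listeners is exact: for syllable scoring
#' `E[score] = i + d/2 - d * sum_j E[p_j]`, and for word scoring the
#' per-word success `rho * p + (1 - rho) * p^2` replaces `p`. The
#' expectation over the listener midpoint distribution is computed by
#' numerical integration against the Normal density.
#'
#' Used to calibrate scenario parameters against target cohort means and as
#' a closed-form check on simulation output.
#'
#' @param spec A [cohort_spec()] object.
#' @param design A [sinb_design()] object.
#' @param ear `"right"` or `"left"` (applies the ear offset).
#' @return Named numeric vector `c(word = , syllable = )`, dB SNR.
#' @export
expected_cohort_scores <- function(spec, design, ear = c("right", "left")) {
  ear <- match.arg(ear)
  stopifnot(inherits(spec, "cohort_spec"), inherits(design, "sinb_design"))
  mu <- spec$threshold_mean_db + if (ear == "left") spec$ear_offset_db else 0
  snr <- level_snrs(design)
  rho <- spec$within_word_dependence
  ep <- function(s) {  # E_T[p(s; T)] with T ~ N(mu, tau^2)
    if (spec$threshold_sd_db == 0) {
      syllable_success_prob(s, mu, spec$slope_db)
    } else {
      stats::integrate(function(t) {
        syllable_success_prob(s, t, spec$slope_db) *
          stats::dnorm(t, mu, spec$threshold_sd_db)
      }, -Inf, Inf, rel.tol = 1e-10)$value
    }
  }
  eq <- function(s) {  # E_T[rho p + (1-rho) p^2]
    if (spec$threshold_sd_db == 0) {
      p <- syllable_success_prob(s, mu, spec$slope_db)
      rho * p + (1 - rho) * p^2
    } else {
      stats::integrate(function(t) {
        p <- syllable_success_prob(s, t, spec$slope_db)
        (rho * p + (1 - rho) * p^2) * stats::dnorm(t, mu, spec$threshold_sd_db)
      }, -Inf, Inf, rel.tol = 1e-10)$value
    }
  }
  base <- design$initial_snr_db + design$step_db / 2
  c(word = base - design$step_db * sum(vapply(snr, eq, numeric(1))),
    syllable = base - design$step_db * sum(vapply(snr, ep, numeric(1))))
}
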