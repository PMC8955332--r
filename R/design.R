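#' Define a Speech-in-Babble presentation design
#'
#' A SinB administration presents a fixed number of bisyllabic words at each
#' of a descending series of signal-to-noise ratios. The design carries the
#' three quantities of the Spearman-Karber threshold formula: the initial
#' (highest) SNR `i`, the step `d` between consecutive levels, and the number
#' of items per level `w`.
#'
#' The default corresponds to the standard Greek SinB protocol: 50 bisyllabic
#' words, ten per level, at +7, +5, +3, +1 and -1 dB SNR, presented at a
#' fixed level of 60 dB HL against multi-talker babble.
#'
#' @param initial_snr_db SNR of the first (easiest) level, in dB.
#' @param step_db Decrement between consecutive levels, in dB; must be
#'   positive.
#' @param n_levels Number of SNR levels (at least 2).
#' @param words_per_level Words presented at each level.
#' @param syllables_per_word Syllables per word (2 for the SinB).
#' @param presentation_level_db_hl Fixed presentation level in dB HL
#'   (informational; does not enter the scoring arithmetic).
#'
#' @return An object of class `"sinb_design"`.
#' @examples
#' des <- sinb_design()
#' level_snrs(des)
#' @export
sinb_design <- function(initial_snr_db = 7,
                        step_db = 2,
                        n_levels = 5L,
                        words_per_level = 10L,
                        syllables_per_word = 2L,
                        presentation_level_db_hl = 60) {
  stopifnot(
    is.numeric(initial_snr_db), length(initial_snr_db) == 1L,
    is.numeric(step_db), length(step_db) == 1L,
    is.numeric(n_levels), length(n_levels) == 1L,
    is.numeric(words_per_level), length(words_per_level) == 1L,
    is.numeric(syllables_per_word), length(syllables_per_word) == 1L
  )
  if (!is.finite(step_db) || step_db <= 0) {
    stop("`step_db` must be a positive number", call. = FALSE)
  }
  n_levels <- as.integer(n_levels)
  words_per_level <- as.integer(words_per_level)
  syllables_per_word <- as.integer(syllables_per_word)
  if (n_levels < 2L) stop("`n_levels` must be at least 2", call. = FALSE)
  if (words_per_level < 1L) stop("`words_per_level` must be at least 1", call. = FALSE)
  if (syllables_per_word < 1L) stop("`syllables_per_word` must be at least 1", call. = FALSE)

  structure(
    list(
      initial_snr_db = as.numeric(initial_snr_db),
      step_db = as.numeric(step_db),
      n_levels = n_levels,
      words_per_level = words_per_level,
      syllables_per_word = syllables_per_word,
      presentation_level_db_hl = as.numeric(presentation_level_db_hl)
    ),
    class = "sinb_design"
  )
}

#' Nominal SNR of each presentation level
#'
#' Level `j` (0-based) is presented at `initial_snr_db - j * step_db`.
#'
#' @param design A [sinb_design()] object.
#' @return Numeric vector of length `n_levels`, in presentation order
#'   (descending SNR).
#' @export
level_snrs <- function(design) {
  stopifnot(inherits(design, "sinb_design"))
  design$initial_snr_db - (seq_len(design$n_levels) - 1L) * design$step_db
}

#' Items per level under a scoring mode
#'
#' Word scoring counts each word as one item; syllable scoring counts each
#' syllable, so the per-level denominator is
#' `words_per_level * syllables_per_word`.
#'
#' @param design A [sinb_design()] object.
#' @param mode `"word"` or `"syllable"`.
#' @return Integer scalar.
#' @export
items_per_level <- function(design, mode = c("word", "syllable")) {
  stopifnot(inherits(design, "sinb_design"))
  mode <- match.arg(mode)
  if (mode == "word") design$words_per_level
  else design$words_per_level * design$syllables_per_word
}

#' Attainable range of the Spearman-Karber score
#'
#' All scores lie in the closed interval
#' `[i + d/2 - d * n_levels, i + d/2]`: the lower bound is attained when
#' every item is correct, the upper bound when none is. For the default
#' design this is \[-2, +8\] dB SNR.
#'
#' @param design A [sinb_design()] object.
#' @return Numeric length-2 vector `c(lower, upper)`.
#' @export
score_range <- function(design) {
  stopifnot(inherits(design, "sinb_design"))
  upper <- design$initial_snr_db + design$step_db / 2
  c(upper - design$step_db * design$n_levels, upper)
}

#' @export
print.sinb_design <- function(x, ...) {
  cat("Speech-in-Babble presentation design\n")
  cat(sprintf("  levels      : %d (SNR %s dB)\n", x$n_levels,
              paste(sprintf("%+g", level_snrs(x)), collapse = ", ")))
  cat(sprintf("  words/level : %d (%d syllables each)\n",
              x$words_per_level, x$syllables_per_word))
  cat(sprintf("  presentation: %g dB HL\n", x$presentation_level_db_hl))
  rng <- score_range(x)
  cat(sprintf("  score range : [%+g, %+g] dB SNR\n", rng[1], rng[2]))
  invisible(x)
}

#' Read or write a design as JSON
#'
#' @param path File path.
#' @param design A [sinb_design()] object.
#' @return `read_design()` returns a `sinb_design`; `write_design()` returns
#'   `path` invisibly.
#' @export
read_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  wanted <- names(formals(sinb_design))
  unknown <- setdiff(names(x), wanted)
  if (length(unknown)) {
    stop("unknown design fields: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(sinb_design, x)
}

#' @rdname read_design
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "sinb_design"))
  jsonlite::write_json(unclass(design), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
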