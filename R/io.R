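#' Read and validate a trial-level CSV
#'
#' The trial schema has one row per presented word: `participant_id`,
#' `group` (`APD`/`control`), `ear` (`right`/`left`), `level_index`
#' (0-based), `snr_db`, `word_id`, `syll1_correct`, `syll2_correct`
#' (0/1). `snr_db` must equal the design's nominal SNR for the row's
#' level; no silent coercion is performed, and validation errors carry row
#' numbers.
#'
#' @param path CSV file path (header mandatory).
#' @param design A [sinb_design()] object used for validation.
#' @return Data frame in the trial schema.
#' @export
read_trials <- function(path, design = sinb_design()) {
  stopifnot(inherits(design, "sinb_design"))
  if (!file.exists(path)) stop_validation("trial file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trials(df, design)
}

#' Validate an in-memory trial table
#'
#' @param trials Data frame in the trial schema.
#' @inheritParams read_trials
#' @return The validated trial table, invisibly unchanged.
#' @export
validate_trials <- function(trials, design = sinb_design()) {
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols)) {
    stop_validation("missing trial columns: ", paste(missing_cols, collapse = ", "))
  }
  bad_group <- which(!trials$group %in% c("APD", "control"))
  if (length(bad_group)) {
    stop_validation("invalid group label at row ", bad_group[1L], ": '",
                    trials$group[bad_group[1L]], "' (expected APD or control)")
  }
  bad_ear <- which(!trials$ear %in% c("right", "left"))
  if (length(bad_ear)) {
    stop_validation("invalid ear at row ", bad_ear[1L], ": '",
                    trials$ear[bad_ear[1L]], "' (expected right or left)")
  }
  lev <- trials$level_index
  bad_lev <- which(!is.finite(lev) | lev != floor(lev) | lev < 0 |
                     lev >= design$n_levels)
  if (length(bad_lev)) {
    stop_validation("level_index out of range 0..", design$n_levels - 1L,
                    " at row ", bad_lev[1L])
  }
  nominal <- level_snrs(design)[lev + 1L]
  bad_snr <- which(abs(trials$snr_db - nominal) > 1e-9)
  if (length(bad_snr)) {
    r <- bad_snr[1L]
    stop_validation("snr_db disagrees with design at row ", r, ": got ",
                    trials$snr_db[r], ", nominal ", nominal[r],
                    " for level ", lev[r])
  }
  for (col in c("syll1_correct", "syll2_correct")) {
    bad <- which(!trials[[col]] %in% c(0L, 1L))
    if (length(bad)) {
      stop_validation(col, " must be 0/1; offending row ", bad[1L])
    }
  }
  # per-administration completeness, with participant/ear context
  key <- paste(trials$participant_id, trials$ear, sep = "\r")
  check_trial_table(trials, design, key)
  invisible(trials)
}

#' Write a trial table to CSV
#'
#' @param trials Data frame in the trial schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials[, trial_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

score_columns <- c("participant_id", "group", "snr50_word_right",
                   "snr50_word_left", "snr50_syll_right", "snr50_syll_left")

#' Read or write a per-participant score CSV
#'
#' One row per participant with the four SNR50 measures (word/syllable by
#' right/left ear, dB SNR) and the group label. Scores are carried at full
#' precision; round only for display.
#'
#' @param path CSV file path.
#' @param scores Data frame as returned by [score_trials()].
#' @return `read_scores()` returns the validated score table;
#'   `write_scores()` returns `path` invisibly.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop_validation("score file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(score_columns, names(df))
  if (length(missing_cols)) {
    stop_validation("missing score columns: ", paste(missing_cols, collapse = ", "))
  }
  measures <- setdiff(score_columns, c("participant_id", "group"))
  for (col in measures) {
    if (!is.numeric(df[[col]]) || anyNA(df[[col]])) {
      stop_validation("score column ", col, " must be numeric and complete")
    }
  }
  if (anyDuplicated(df$participant_id)) {
    stop_validation("duplicate participant_id in score table: ",
                    df$participant_id[duplicated(df$participant_id)][1L])
  }
  df
}

#' @rdname read_scores
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(scores[, score_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
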