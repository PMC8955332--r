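#' @keywords internal
stop_validation <- function(...) {
  msg <- paste0(...)
  cond <- structure(
    class = c("sinb_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

trial_columns <- c("participant_id", "group", "ear", "level_index",
                   "snr_db", "word_id", "syll1_correct", "syll2_correct")

# Completeness/duplication check for one single-ear administration.
# Returns invisibly; errors name the offending (level, word) slots.
check_administration <- function(trials, design, context = "") {
  need <- c("level_index", "word_id", "syll1_correct", "syll2_correct")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols)) {
    stop_validation("missing trial columns: ", paste(missing_cols, collapse = ", "))
  }
  ctx <- if (nzchar(context)) paste0(" [", context, "]") else ""
  lev <- trials$level_index
  if (any(!is.finite(lev)) || any(lev != floor(lev)) ||
      any(lev < 0) || any(lev >= design$n_levels)) {
    stop_validation("level_index out of range 0..", design$n_levels - 1L, ctx)
  }
  key <- paste(lev, trials$word_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    parts <- strsplit(dup, "\r", fixed = TRUE)[[1L]]
    stop_validation("duplicate trial record for (level ", parts[1L],
                    ", word ", parts[2L], ")", ctx)
  }
  per_level <- tabulate(lev + 1L, nbins = design$n_levels)
  bad <- which(per_level != design$words_per_level)
  if (length(bad)) {
    j <- bad[1L]
    if (per_level[j] < design$words_per_level) {
      stop_validation("incomplete administration: level ", j - 1L, " has ",
                      per_level[j], " of ", design$words_per_level, " words", ctx)
    }
    stop_validation("level ", j - 1L, " has ", per_level[j],
                    " words, expected ", design$words_per_level, ctx)
  }
  s1 <- trials$syll1_correct
  s2 <- trials$syll2_correct
  if (!all(s1 %in% c(0, 1)) || !all(s2 %in% c(0, 1))) {
    stop_validation("syllable correctness flags must be 0/1", ctx)
  }
  invisible(trials)
}

#' Count correct items per SNR level
#'
#' Applies the SinB item-scoring rule to one complete single-ear
#' administration. Under word scoring a word counts as correct only when
#' both of its syllables were repeated correctly; a word with exactly one
#' correct syllable is incorrect. Under syllable scoring every correctly
#' repeated syllable counts as one item, so the same word contributes up to
#' `syllables_per_word` items.
#'
#' @param trials Data frame of trial records for one participant and one
#'   ear, with columns `level_index` (0-based), `word_id`, `syll1_correct`
#'   and `syll2_correct` (0/1).
#' @param mode `"word"` or `"syllable"`.
#' @param design A [sinb_design()] object governing the administration.
#'
#' @return Integer vector of per-level correct-item counts, in level order
#'   (index 0 first). Incomplete or duplicated administrations raise a
#'   validation error naming the offending level and word.
#' @examples
#' trials <- simulate_administration(c(right = 1), sinb_design(),
#'                                   rho = 0.3, slope_db = 1)
#' count_correct_items(trials, "word", sinb_design())
#' count_correct_items(trials, "syllable", sinb_design())
#' @export
count_correct_items <- function(trials, mode = c("word", "syllable"), design) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "sinb_design"))
  check_administration(trials, design)
  item <- if (mode == "word") {
    as.numeric(trials$syll1_correct & trials$syll2_correct)
  } else {
    trials$syll1_correct + trials$syll2_correct
  }
  counts <- vapply(seq_len(design$n_levels) - 1L, function(j) {
    sum(item[trials$level_index == j])
  }, numeric(1))
  as.integer(counts)
}

#' Spearman-Karber SNR50 threshold
#'
#' Computes the SNR at which half the items are recognised, from per-level
#' correct counts on a descending fixed-level series:
#' `SNR50 = i + d/2 - d * sum(counts) / w`, where `i` is the initial SNR,
#' `d` the step and `w` the items per level for the scoring mode. Higher
#' scores mean poorer performance. With every item correct the score reaches
#' the lower end of [score_range()]; with none correct, the upper end.
#'
#' @param correct_counts Integer vector of per-level correct-item counts
#'   (level 0 first), one entry per design level.
#' @param design A [sinb_design()] object.
#' @param mode `"word"` or `"syllable"`; fixes the per-level denominator.
#'
#' @return The SNR50 estimate in dB SNR (full precision; round only for
#'   display).
#' @examples
#' des <- sinb_design()
#' spearman_karber(c(10, 10, 8, 5, 2), des, "word")    # +1.0 dB
#' spearman_karber(c(20, 20, 18, 12, 6), des, "syllable") # +0.4 dB
#' @export
spearman_karber <- function(correct_counts, design, mode = c("word", "syllable")) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "sinb_design"))
  if (length(correct_counts) != design$n_levels) {
    stop_validation("expected ", design$n_levels, " per-level counts, got ",
                    length(correct_counts))
  }
  w <- items_per_level(design, mode)
  if (any(!is.finite(correct_counts)) || any(correct_counts < 0) ||
      any(correct_counts > w)) {
    stop_validation("correct counts must lie in 0..", w, " for ", mode, " scoring")
  }
  design$initial_snr_db + design$step_db / 2 -
    design$step_db * sum(correct_counts) / w
}

# Vectorised completeness/duplication validation for a whole trial table.
# `split_key` identifies one administration (participant + ear). Errors name
# the offending participant, ear, level and word.
check_trial_table <- function(trials, design, split_key) {
  lev <- trials$level_index
  if (any(!is.finite(lev)) || any(lev != floor(lev)) ||
      any(lev < 0) || any(lev >= design$n_levels)) {
    r <- which(!is.finite(lev) | lev != floor(lev) | lev < 0 |
                 lev >= design$n_levels)[1L]
    stop_validation("level_index out of range 0..", design$n_levels - 1L,
                    " at row ", r)
  }
  ctx_of <- function(key) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    paste0("participant ", parts[1L], ", ", parts[2L], " ear")
  }
  full_key <- paste(split_key, lev, trials$word_id, sep = "\r")
  if (anyDuplicated(full_key)) {
    d <- full_key[duplicated(full_key)][1L]
    parts <- strsplit(d, "\r", fixed = TRUE)[[1L]]
    stop_validation("duplicate trial record for (level ", parts[3L],
                    ", word ", parts[4L], ") [participant ", parts[1L],
                    ", ", parts[2L], " ear]")
  }
  kl <- paste(split_key, lev, sep = "\r")
  n_per <- rowsum(rep(1L, length(kl)), kl, reorder = FALSE)
  bad <- which(n_per[, 1L] != design$words_per_level)
  if (length(bad)) {
    parts <- strsplit(rownames(n_per)[bad[1L]], "\r", fixed = TRUE)[[1L]]
    n_got <- n_per[bad[1L], 1L]
    if (n_got < design$words_per_level) {
      stop_validation("incomplete administration: level ", parts[3L],
                      " has ", n_got, " of ", design$words_per_level,
                      " words [participant ", parts[1L], ", ", parts[2L],
                      " ear]")
    }
    stop_validation("level ", parts[3L], " has ", n_got,
                    " words, expected ", design$words_per_level,
                    " [participant ", parts[1L], ", ", parts[2L], " ear]")
  }
  # every administration must cover all levels
  levels_per_admin <- rowsum(rep(1L, nrow(n_per)),
                             sub("\r[^\r]*$", "", rownames(n_per)),
                             reorder = FALSE)
  short <- which(levels_per_admin[, 1L] != design$n_levels)
  if (length(short)) {
    k <- rownames(levels_per_admin)[short[1L]]
    seen <- as.integer(sub(".*\r", "", grep(paste0("^", k, "\r"),
                                            rownames(n_per), value = TRUE,
                                            fixed = FALSE)))
    missing_lev <- setdiff(seq_len(design$n_levels) - 1L, seen)
    stop_validation("incomplete administration: level ", missing_lev[1L],
                    " has 0 of ", design$words_per_level, " words [",
                    ctx_of(k), "]")
  }
  if (!all(trials$syll1_correct %in% c(0, 1)) ||
      !all(trials$syll2_correct %in% c(0, 1))) {
    stop_validation("syllable correctness flags must be 0/1")
  }
  invisible(trials)
}

#' Score one participant's full administration
#'
#' Derives all four SinB measures — word-based and syllable-based SNR50 for
#' each ear — from a single administration, as the test protocol prescribes.
#' Syllable scores can never exceed word scores on the same data: every
#' correct word contributes all its syllables, while partially correct words
#' add syllables only under syllable scoring.
#'
#' @param trials Data frame of trial records for one participant, both ears
#'   (`ear` column with values `"right"` and `"left"` plus the columns of
#'   [count_correct_items()]).
#' @param design A [sinb_design()] object.
#'
#' @return One-row data frame with columns `snr50_word_right`,
#'   `snr50_word_left`, `snr50_syll_right`, `snr50_syll_left` (dB SNR).
#' @export
score_administration <- function(trials, design) {
  stopifnot(inherits(design, "sinb_design"))
  if (!"ear" %in% names(trials)) stop_validation("missing trial column: ear")
  out <- list()
  for (e in c("right", "left")) {
    sub <- trials[trials$ear == e, , drop = FALSE]
    if (nrow(sub) == 0L) stop_validation("no trials for ", e, " ear")
    res <- tryCatch(
      {
        cw <- count_correct_items(sub, "word", design)
        cs <- count_correct_items(sub, "syllable", design)
        list(word = spearman_karber(cw, design, "word"),
             syll = spearman_karber(cs, design, "syllable"))
      },
      sinb_validation_error = function(cnd) {
        stop_validation(conditionMessage(cnd), " [", e, " ear]")
      }
    )
    out[[paste0("snr50_word_", e)]] <- res$word
    out[[paste0("snr50_syll_", e)]] <- res$syll
  }
  data.frame(
    snr50_word_right = out$snr50_word_right,
    snr50_word_left  = out$snr50_word_left,
    snr50_syll_right = out$snr50_syll_right,
    snr50_syll_left  = out$snr50_syll_left
  )
}

#' Score a trial table for all participants
#'
#' Vectorised scoring of a full trial table (any number of participants,
#' both ears). Every administration is validated for completeness and
#' duplicates before scoring; no imputation of missing trials is attempted.
#'
#' @param trials Data frame in the trial schema (columns `participant_id`,
#'   `group`, `ear`, `level_index`, `word_id`, `syll1_correct`,
#'   `syll2_correct`; `snr_db` optional here, validated by [read_trials()]).
#' @param design A [sinb_design()] object.
#'
#' @return Data frame with one row per participant: `participant_id`,
#'   `group`, and the four SNR50 measures in dB SNR.
#' @export
score_trials <- function(trials, design) {
  stopifnot(inherits(design, "sinb_design"))
  need <- c("participant_id", "group", "ear", "level_index", "word_id",
            "syll1_correct", "syll2_correct")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols)) {
    stop_validation("missing trial columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(trials$ear %in% c("right", "left"))) {
    stop_validation("ear must be 'right' or 'left'")
  }
  pid <- as.character(trials$participant_id)
  ids <- unique(pid)
  split_key <- paste(pid, trials$ear, sep = "\r")
  check_trial_table(trials, design, split_key)
  grp <- as.character(trials$group[match(ids, pid)])

  word_item <- as.numeric(trials$syll1_correct & trials$syll2_correct)
  syll_item <- trials$syll1_correct + trials$syll2_correct
  i <- design$initial_snr_db
  d <- design$step_db

  score_one <- function(item, per_level_items) {
    tot <- rowsum(item, split_key, reorder = FALSE)
    tot_by_key <- tot[, 1L]
    names(tot_by_key) <- rownames(tot)
    i + d / 2 - d * tot_by_key / per_level_items
  }
  sw <- score_one(word_item, items_per_level(design, "word"))
  ss <- score_one(syll_item, items_per_level(design, "syllable"))

  key_of <- function(id, ear) paste(id, ear, sep = "\r")
  data.frame(
    participant_id = ids,
    group = grp,
    snr50_word_right = unname(sw[key_of(ids, "right")]),
    snr50_word_left  = unname(sw[key_of(ids, "left")]),
    snr50_syll_right = unname(ss[key_of(ids, "right")]),
    snr50_syll_left  = unname(ss[key_of(ids, "left")]),
    stringsAsFactors = FALSE
  )
}
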