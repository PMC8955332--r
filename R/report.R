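#' Cohort summary table of means and SDs
#'
#' @param scores Per-participant score table.
#' @return Data frame with one row per group x measure: `group`, `measure`,
#'   `n`, `mean`, `sd` (dB SNR, full precision).
#' @export
summarize_scores <- function(scores) {
  measures <- setdiff(score_columns, c("participant_id", "group"))
  rows <- list()
  for (g in unique(scores$group)) {
    sub <- scores[scores$group == g, , drop = FALSE]
    for (m in measures) {
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, measure = m, n = nrow(sub),
        mean = mean(sub[[m]]), sd = stats::sd(sub[[m]]),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Full cohort-comparison analysis
#'
#' Runs the complete statistical sequence on a per-participant score table:
#' normality screen (skewness/kurtosis z), cohort summary (means/SDs),
#' Cohen's d per measure, the omnibus 2x2x2 mixed ANOVA
#' (group x scoring x ear), per-ear 2x2 mixed ANOVAs (group x scoring), and
#' per-measure one-way ANOVAs. All statistics are computed at full
#' precision; rounding happens only in the printed report.
#'
#' @param scores Per-participant score table ([score_trials()] or
#'   [read_scores()] output) with at least two participants per group.
#' @return An object of class `"sinb_report"`: a list with elements
#'   `normality`, `summary`, `effect_sizes`, `omnibus`, `per_ear`
#'   (list `right`/`left`), `per_measure`, `n_per_group`.
#' @export
analyze_scores <- function(scores) {
  group <- factor(scores$group)
  if (nlevels(group) < 2L) {
    stop_validation("analysis needs two groups; found only '",
                    levels(group)[1L], "'")
  }
  n_g <- table(group)
  if (any(n_g < 2L)) stop_validation("each group needs at least 2 participants")
  if (any(n_g < 5L)) {
    warning("fewer than 5 participants in a group; statistics will be ",
            "severely underpowered", call. = FALSE)
  }
  measures <- setdiff(score_columns, c("participant_id", "group"))
  per_measure <- do.call(rbind, lapply(measures, function(m) {
    cbind(measure = m, one_way_anova(scores[[m]], scores$group))
  }))
  structure(
    list(
      normality = normality_screen(scores),
      summary = summarize_scores(scores),
      effect_sizes = cohort_effect_sizes(scores),
      omnibus = mixed_anova(scores, within = c("scoring", "ear")),
      per_ear = list(
        right = mixed_anova(scores, within = "scoring", ear = "right"),
        left  = mixed_anova(scores, within = "scoring", ear = "left")
      ),
      per_measure = per_measure,
      n_per_group = as.list(n_g)
    ),
    class = "sinb_report"
  )
}

fmt_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))

#' @export
print.sinb_report <- function(x, digits = 2, ...) {
  cat("Speech-in-Babble cohort comparison\n")
  cat(sprintf("  groups: %s\n\n",
              paste(sprintf("%s (n=%d)", names(x$n_per_group),
                            unlist(x$n_per_group)), collapse = ", ")))
  cat("Cohort means (SD), dB SNR:\n")
  s <- x$summary
  for (g in unique(s$group)) {
    sub <- s[s$group == g, ]
    cat(sprintf("  %-8s %s\n", g,
                paste(sprintf("%s %.*f (%.*f)",
                              sub("snr50_", "", sub$measure),
                              digits, sub$mean, digits, sub$sd),
                      collapse = "  ")))
  }
  npass <- x$normality$pass
  cat("\nNormality screen (skew/kurtosis z in ±1.96): ",
      if (anyNA(npass)) "not evaluated (group too small)"
      else if (all(npass)) "all pass"
      else paste(sum(!npass), "of", length(npass), "fail"),
      "\n", sep = "")
  cat("\nCohen's d (APD vs control):\n")
  es <- x$effect_sizes
  cat(paste(sprintf("  %-18s %.3f", sub("snr50_", "", es$measure), es$d),
            collapse = "\n"), "\n")
  cat("\nOmnibus mixed ANOVA (group x scoring x ear):\n")
  om <- x$omnibus
  cat(paste(sprintf("  %-18s F(%d, %d) = %8.3f, p = %s", om$effect, om$df1,
                    om$df2, om$F, fmt_p(om$p)), collapse = "\n"), "\n")
  for (e in c("right", "left")) {
    pe <- x$per_ear[[e]]
    cat(sprintf("\n%s-ear 2x2 ANOVA (group x scoring):\n", e))
    cat(paste(sprintf("  %-18s F(%d, %d) = %8.3f, p = %s", pe$effect, pe$df1,
                      pe$df2, pe$F, fmt_p(pe$p)), collapse = "\n"), "\n")
  }
  cat("\nPer-measure one-way ANOVA:\n")
  pm <- x$per_measure
  cat(paste(sprintf("  %-18s F(%d, %d) = %8.3f, p = %s",
                    sub("snr50_", "", pm$measure), pm$df1, pm$df2, pm$F,
                    fmt_p(pm$p)), collapse = "\n"), "\n")
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits a machine-readable CSV of all test statistics alongside the
#' human-readable text report.
#'
#' @param report A [analyze_scores()] result.
#' @param path Output path stem; writes `<path>.txt` and `<path>.csv`.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "sinb_report"))
  txt <- paste0(path, ".txt")
  csv <- paste0(path, ".csv")
  writeLines(utils::capture.output(print(report)), txt)

  blocks <- list(
    cbind(section = "summary",
          report$summary[c("group", "measure")],
          statistic = "mean_sd",
          value = report$summary$mean, extra = report$summary$sd),
    cbind(section = "effect_size",
          group = "APD_vs_control", measure = report$effect_sizes$measure,
          statistic = "cohens_d", value = report$effect_sizes$d, extra = NA),
    cbind(section = "omnibus_anova", group = "both",
          measure = "all", statistic = report$omnibus$effect,
          value = report$omnibus$F, extra = report$omnibus$p),
    cbind(section = "right_ear_anova", group = "both", measure = "right",
          statistic = report$per_ear$right$effect,
          value = report$per_ear$right$F, extra = report$per_ear$right$p),
    cbind(section = "left_ear_anova", group = "both", measure = "left",
          statistic = report$per_ear$left$effect,
          value = report$per_ear$left$F, extra = report$per_ear$left$p),
    cbind(section = "one_way_anova", group = "both",
          measure = report$per_measure$measure, statistic = "F",
          value = report$per_measure$F, extra = report$per_measure$p)
  )
  out <- do.call(rbind, lapply(blocks, function(b) {
    as.data.frame(b, stringsAsFactors = FALSE)
  }))
  utils::write.csv(out, csv, row.names = FALSE)
  invisible(c(txt, csv))
}
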