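des <- sinb_design()

test_that("item counting applies the word and syllable rules", {
  # all ten words fully correct at every level
  all_correct <- build_administration(replicate(5, level_outcomes(10, 0),
                                                simplify = FALSE))
  expect_equal(count_correct_items(all_correct, "word", des),
               rep(10L, 5))
  expect_equal(count_correct_items(all_correct, "syllable", des),
               rep(20L, 5))

  # one word with a single correct syllable: incorrect as a word,
  # one item as a syllable
  mixed <- build_administration(c(
    list(level_outcomes(9, 1)), replicate(4, level_outcomes(10, 0),
                                          simplify = FALSE)
  ))
  expect_equal(count_correct_items(mixed, "word", des)[1L], 9L)
  expect_equal(count_correct_items(mixed, "syllable", des)[1L], 19L)

  # 6 full + 3 half + 1 none -> 6 words, 15 syllables
  part <- build_administration(c(
    list(level_outcomes(6, 3)), replicate(4, level_outcomes(10, 0),
                                          simplify = FALSE)
  ))
  expect_equal(count_correct_items(part, "word", des)[1L], 6L)
  expect_equal(count_correct_items(part, "syllable", des)[1L], 15L)
})

test_that("incomplete and duplicated administrations are rejected by name", {
  trials <- build_administration(replicate(5, level_outcomes(10, 0),
                                           simplify = FALSE))
  expect_error(count_correct_items(trials[-3, ], "word", des),
               "level 0 has 9 of 10 words")
  dup <- rbind(trials, trials[7, ])
  expect_error(count_correct_items(dup, "word", des),
               "duplicate trial record for \\(level 0, word L0_W07\\)")
  extra <- rbind(trials, within(trials[1, ], word_id <- "L0_W11"))
  expect_error(count_correct_items(extra, "word", des), "11 words, expected 10")
})

test_that("the Spearman-Karber estimator reproduces worked values", {
  expect_identical(spearman_karber(rep(10L, 5), des, "word"), -2)
  expect_identical(spearman_karber(rep(0L, 5), des, "word"), 8)
  expect_identical(spearman_karber(rep(0L, 5), des, "syllable"), 8)
  expect_equal(spearman_karber(c(10, 10, 8, 5, 2), des, "word"), 1.0)
  expect_equal(spearman_karber(c(20, 20, 18, 12, 6), des, "syllable"), 0.4)
  expect_error(spearman_karber(c(10, 10, 8, 5), des, "word"), "5 per-level")
  expect_error(spearman_karber(c(11, 10, 8, 5, 2), des, "word"), "0..10")
  expect_error(spearman_karber(c(10, 10, 8, 5, -1), des, "word"), "0..10")
  expect_error(spearman_karber(c(21, 10, 8, 5, 2), des, "syllable"), "0..20")
})

test_that("estimator equals the per-level summation oracle and is monotone", {
  set.seed(101)
  for (k in 1:500) {
    counts <- sample(0:10, 5, replace = TRUE)
    got <- spearman_karber(counts, des, "word")
    expect_equal(got, oracle_sk(counts, des, "word"), tolerance = 1e-13)
    rng <- score_range(des)
    expect_gte(got, rng[1])
    expect_lte(got, rng[2])
    # one more correct item anywhere lowers the score by exactly d/w
    j <- sample(which(counts < 10), 1)
    bumped <- counts
    bumped[j] <- bumped[j] + 1L
    expect_equal(spearman_karber(bumped, des, "word"), got - 2 / 10)
  }
  # also on a non-default design
  des2 <- sinb_design(initial_snr_db = 4, step_db = 1.5, n_levels = 7,
                      words_per_level = 6, syllables_per_word = 3)
  for (k in 1:100) {
    counts <- sample(0:18, 7, replace = TRUE)
    expect_equal(spearman_karber(counts, des2, "syllable"),
                 oracle_sk(counts, des2, "syllable"), tolerance = 1e-13)
  }
})

test_that("score_administration composes counting and estimation per ear", {
  right <- build_administration(replicate(5, level_outcomes(10, 0),
                                          simplify = FALSE), ear = "right")
  left <- build_administration(replicate(5, level_outcomes(10, 0),
                                         simplify = FALSE), ear = "left")
  ss <- score_administration(rbind(right, left), des)
  expect_equal(unlist(ss), c(snr50_word_right = -2, snr50_word_left = -2,
                             snr50_syll_right = -2, snr50_syll_left = -2))

  # word counts (10,10,8,5,2); every incorrect word fully incorrect
  # -> word and syllable scores coincide at +1.0
  full_miss <- build_administration(lapply(c(10, 10, 8, 5, 2), function(n)
    level_outcomes(n, 0)), ear = "right")
  ss2 <- score_administration(rbind(full_miss, left), des)
  expect_equal(ss2$snr50_word_right, 1.0)
  expect_identical(ss2$snr50_syll_right, ss2$snr50_word_right)

  # same word counts but every incorrect word half right -> syllable -0.5
  half_miss <- build_administration(lapply(c(10, 10, 8, 5, 2), function(n)
    level_outcomes(n, 10L - n)), ear = "right")
  ss3 <- score_administration(rbind(half_miss, left), des)
  expect_equal(ss3$snr50_word_right, 1.0)
  expect_equal(ss3$snr50_syll_right, -0.5)
  expect_lt(ss3$snr50_syll_right, ss3$snr50_word_right)

  # errors identify the ear
  expect_error(score_administration(rbind(full_miss[-1, ], left), des),
               "right ear")
})

test_that("scores depend on trials only through per-level counts", {
  set.seed(77)
  outs <- replicate(5, level_outcomes(sample(0:8, 1), sample(0:2, 1)),
                    simplify = FALSE)
  right <- build_administration(outs, ear = "right")
  left <- build_administration(outs, ear = "left")
  base <- score_administration(rbind(right, left), des)
  shuffled <- rbind(right[sample(nrow(right)), ], left[sample(nrow(left)), ])
  expect_equal(score_administration(shuffled, des), base)
})

test_that("syllable scores never exceed word scores (dominance)", {
  set.seed(404)
  for (k in 1:60) {
    outs <- replicate(5, {
      n_both <- sample(0:10, 1)
      level_outcomes(n_both, sample(0:(10 - n_both), 1))
    }, simplify = FALSE)
    right <- build_administration(outs, ear = "right")
    left <- build_administration(outs, ear = "left")
    ss <- score_administration(rbind(right, left), des)
    expect_lte(ss$snr50_syll_right, ss$snr50_word_right)
    any_partial <- any(vapply(outs, function(m) any(m[, 1] != m[, 2]),
                              logical(1)))
    if (!any_partial) {
      expect_identical(ss$snr50_syll_right, ss$snr50_word_right)
    } else {
      expect_lt(ss$snr50_syll_right, ss$snr50_word_right)
    }
  }
})

test_that("score_trials scores whole tables and matches per-participant scoring", {
  cfg <- sinb_scenario("default", seed = 42)
  trials <- simulate_cohorts(cfg)
  scores <- score_trials(trials, cfg$design)
  expect_equal(nrow(scores), 55L)
  expect_setequal(scores$group[!duplicated(scores$group)], c("control", "APD"))
  # spot-check against the one-participant path
  for (pid in scores$participant_id[c(1, 20, 40)]) {
    one <- score_administration(trials[trials$participant_id == pid, ],
                                cfg$design)
    got <- scores[scores$participant_id == pid, names(one)]
    expect_equal(unname(unlist(got)), unname(unlist(one)))
  }
  # errors carry participant and ear context
  broken <- trials[-5, ]
  expect_error(score_trials(broken, cfg$design),
               "participant control001, right ear")
})
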