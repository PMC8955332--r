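---
title: "Methods: scoring granularity, simulation and statistics for the SinB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring granularity, simulation and statistics for the SinB}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinbscore)
```

## The test and the two item definitions

The Greek Speech-in-Babble test presents 50 bisyllabic words in
multi-talker babble at 60 dB HL, ten words at each of five fixed
signal-to-noise ratios (+7, +5, +3, +1, −1 dB), separately for each ear.
The listener repeats each word; the outcome of a trial is the pair of
per-syllable correctness flags.

One administration supports two item definitions:

* **word scoring** — an item is a whole word, correct only when both
  syllables are repeated correctly (10 items per level);
* **syllable scoring** — an item is a single syllable (20 items per
  level), so a half-right word contributes one item instead of zero.

A response containing neither syllable is simply both flags false; the
verbal attention cue preceding each word has no scoring consequence. Both
choices follow from the scoring sheet carrying only the two per-syllable
flags.

## The Spearman–Kärber SNR50

With per-level correct counts $c_j$ and $w$ items per level, the package
computes

$$\mathrm{SNR50} = i + \tfrac{d}{2} - d\,\frac{\sum_j c_j}{w},$$

with $i$ the initial SNR (+7 dB), $d$ the step (2 dB). We read the
"correct score" of the classical formula as the total count over all
levels with $w$ the *per-level* item count: this is the standard
Spearman–Kärber estimator on a truncated descending series, and the only
reading under which the all-correct and none-correct administrations give
finite scores at the ends of the design range ($[-2, +8]$ dB here; the
estimator implicitly assumes everything is correct above the easiest level
and nothing below the hardest). Properties the tests exercise:

* equivalence with a per-level proportion summation to $10^{-13}$;
* strict monotonicity — one extra correct item lowers the score by exactly
  $d/w$;
* permutation invariance — only per-level counts matter, not word order;
* **dominance** — the syllable score never exceeds the word score on the
  same trials, with equality exactly when no word was half-correct. This
  is the mechanism by which syllable scoring can only reveal, never hide,
  partial recognition.

Scores are carried at full precision and rounded only for display (0.01 dB
in reports). Incomplete or duplicated administrations are rejected with
the offending participant, ear, level and word named; no imputation rule
exists for this test, so none is invented.

## The synthetic listener model

The generator exists so the scoring and statistics can be verified end to
end without clinical data. A listener's probability of repeating a
syllable at SNR $s$ is logistic,

$$p(s) = \frac{1}{1 + e^{-(s - T)/\sigma}},$$

with midpoint $T$ (dB SNR) and scale $\sigma$ (dB). The guess rate is
zero: open-set repetition of a word in babble has essentially no chance
success. The two syllables of a word share one $p$ and are coupled by a
*shared-draw mixture*: with probability $\rho$ a single Bernoulli($p$)
draw is copied to both syllables, otherwise they are independent, giving
$P(\text{both}) = \rho p + (1-\rho)p^2$ in closed form — trivially
testable, unlike a copula. $\rho$ is the only mechanism for within-word
dependence; per-syllable difficulty offsets (some syllables are
acoustically more robust than others) are an extension point, not a
default.

Listener midpoints are drawn as $T = \mu_g + \delta_{\text{ear}} +
\varepsilon_i$ with $\varepsilon_i \sim N(0, \tau^2)$ drawn **once per
listener** and shared by both ears. The alternative — independent per-ear
draws — would leave a listener's two ears uncorrelated, which contradicts
the repeated-measures structure the mixed ANOVA is built on; a single
listener effect plus a fixed ear offset is the simplest model with the
right covariance. Group-by-ear interactions are representable by giving
the cohorts different offsets.

Because the estimator is linear in the counts, the *expected* SK score of
a cohort has a closed form (`expected_cohort_scores()`), which the tests
use as an oracle against simulated means and the calibration uses as its
objective.

## The shipped reference scenario

`sinb_scenario("default")` encodes the study conditions of the clinical
scoring comparison: 33 typically developing and 22 APD children, standard
design, both ears. Its parameters are produced by
`scripts/tune_scenario.R`, which solves (deterministically, by
root-finding on the closed-form expectation — no simulation, no grid):

1. shared slope fixed at $\sigma = 1.4$ dB, a typical value for word
   recognition in babble;
2. per cohort, $\rho$ such that the expected word−syllable score gap
   matches the published gap averaged over ears (tuned values ≈ 0.07 for
   both cohorts);
3. per cohort and ear, $\mu$ such that the expected syllable score equals
   the published cohort mean.

The resulting expected means reproduce all eight published cohort means to
better than 0.05 dB. The published left-ear control advantage (0.55 vs
0.93 dB word-based) is reproduced by the control ear offset without being
interpreted.

Between-listener spreads are fixed a priori at $\tau = 0.3$ dB (control)
and $0.6$ dB (APD), mirroring the ordering of the published cohort SDs.
They cannot be *fitted* to those SDs: with 10 words (20 syllables) per
level, the binomial sampling noise of a single administration alone gives
the SK score a standard deviation of roughly 0.4–0.6 dB, which already
exceeds the published control SDs of 0.07–0.11 dB. No non-negative $\tau$
reaches them; the scenario therefore matches means, not SDs, and simulated
cohort SDs (≈ 0.4–0.7 dB) are realistic for the design even though they
are larger than the published ones. This also means simulated per-measure
F values are smaller than the published ones at the same mean separation —
the *pattern* (direction of every contrast, dominance of syllable scoring,
positive group × scoring interaction) is the reproduction target, not the
printed statistics.

What the generator does **not** emulate: babble acoustics, lexical
frequency and phonetic content of the word lists, stress/rhythm effects,
attention lapses, and any syllable-position effects. Passing tests
therefore show the pipeline's arithmetic and statistical machinery are
correct under a plausible listener model — not that the model captures
every feature of clinical data.

## Statistics

* **Normality screen** — adjusted skewness $g_1$ and excess kurtosis
  $g_2$ divided by their small-sample standard errors,
  $SE(g_1) = \sqrt{6n(n-1)/((n-2)(n+1)(n+3))}$ and
  $SE(g_2) = 2\,SE(g_1)\sqrt{(n^2-1)/((n-3)(n+5))}$; pass when both z lie
  in ±1.96. Groups under $n = 8$ are reported as not evaluated rather than
  extrapolating the SEs.
* **Cohen's d** — $(m_2 - m_1)/\sqrt{(SD_1^2 + SD_2^2)/2}$, positive when
  the APD mean is larger. On the published right-ear word moments
  (0.93 ± 0.11 vs 1.33 ± 0.28) this formula gives 1.880, not the published
  0.832; no standard reading of the denominator (SD, SE, CI half-width)
  recovers the published values from the published moments, so the package
  computes the formula faithfully and documents the divergence instead of
  matching the printed numbers.
* **Mixed ANOVA** — group between subjects, scoring and/or ear within, via
  a multivariate linear model with repeated-measures contrasts
  (`car::Anova`, Type III with sum-to-zero contrasts). With unbalanced
  groups (22 vs 33) this is the unweighted-marginal-means analysis; the
  tests verify every F against a from-first-principles stratified
  sums-of-squares oracle (subject means for the between stratum,
  per-subject contrasts for each within stratum) and, for balanced groups,
  against `aov()` error strata. Degrees of freedom are reported as
  $(1, n_{\text{total}} - 2)$ — (1, 53) for the study sizes; the published
  (1, 54) is a df anomaly this package does not emulate. Error strata with
  no residual variance raise a classed degenerate-variance error instead
  of an unbounded F.
* **One-way ANOVAs** per measure use `stats::lm`/`anova`; F equals the
  pooled-variance $t^2$, which the tests assert to $10^{-10}$. No
  multiple-testing correction is applied anywhere, matching the analysis
  being emulated.

## Problem sizes and numerical choices

The automated checks run at these sizes, chosen to make Monte-Carlo error
comfortably smaller than the tolerances they use: $10^4$ random count
vectors for the estimator oracle; $10^4$ simulated administrations for the
dominance property; 500 listeners per group for threshold recovery (mean
syllable score within ±0.5 dB of the generating midpoint, group difference
within ±0.2 dB — the residual is SK truncation bias at the edges of the
level series); 200 replicate studies for the stability of the group
pattern; 1000 replicate null studies for the type-I error of the group
test (covered by the 95% binomial band around 0.05). Simulation is fully
vectorised and seeded once per scenario, so a configuration and seed
reproduce trial tables byte for byte.

## Limitations

Thresholds, sensitivity/specificity cut-offs, test–retest reliability and
phoneme- or stress-level scoring are out of scope. The simulator's
calibration targets are cohort *means*; it deliberately does not chase the
published SDs (see above), so absolute F values and d values from
simulation should be compared between scoring modes, not against the
published table. Real listeners may violate the logistic-with-shared-p
assumption in ways that matter for fine-grained scoring comparisons.
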