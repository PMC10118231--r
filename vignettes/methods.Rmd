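---
title: "Models and methods behind vasmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vasmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasmeta)
```

# The measurement problem

Studies of clinicians' statistical literacy increasingly collect, for
each true/false claim, a *single* double-sided visual analog scale
(VAS) response: a slider from "I am sure this claim is incorrect"
(−100) through "I do not know" (0) to "I am sure it is correct" (+100).
The sign is the first-order answer; the magnitude is the second-order
confidence judgment. This package implements the arithmetic that turns
such responses into calibration and discrimination analyses, the
Bayesian screening task that typically accompanies them, and the
contingency statistics such studies report.

# Scoring model

## Decoding and the distance score

`decode_vas()` maps x to a verdict (`asserts_true` / `asserts_false` /
`unknown`) and confidence |x|. `distance_score()` combines correctness
c ∈ {+1, −1} and confidence into

$$d = \frac{|c\,\mathrm{sign}(x)\,100 - x|}{2} \;=\; 50 - c\,\frac{|x|}{2},$$

so d < 50 iff the answer is correct (for x ≠ 0) and the distance from
50 is half the confidence.

**The x = 0 discontinuity.** Evaluated literally at x = 0 the formula
gives d = 0, which would score a "don't know" as a maximally confident
correct answer. The center of the scale means "I answered randomly", so
we define d(0) = 50 by convention and document the discontinuity. This
is the only point where the closed form and the literal formula
disagree, and the package tests assert their agreement everywhere else
on the integer scale.

**Unknown-verdict policy.** Whether x = 0 responses count as incorrect
or are excluded from accuracy counts is a genuine free choice; both are
supported (`unknown_policy`), defaulting to `incorrect` because the
performance metric is a count of correct answers and a random answer is
not one. Under `excluded`, x = 0 rows drop out of accuracy *and*
confidence aggregation but still count as answered.

## Probability scale

Confidence is kept on the raw 0–100 scale internally; for presentation
against accuracy the map `to_probability_scale()` (x/2 + 50) rescales
it to 50–100, i.e. the subjective probability of being correct implied
by a symmetric two-alternative judgment. Keeping one canonical internal
scale avoids double-transformed means.

# Screening task

`ppv()`/`npv()` are the exact Bayes formulas. `cp_to_nf()` renders the
same parameters as counts in a reference population; with
`rounding = "none"` the rendering is lossless and
`nf_to_ppv(cp_to_nf(p, N))` equals `ppv(p)` to machine precision (a
tested identity), while `rounding = "nearest"` reproduces the integer
tables used in teaching materials.

**Answer classification.** Estimates are labelled by closed windows:
correct at 26 ± 5, confusion-with-sensitivity at 90 ± 1,
confusion-with-specificity at 99 ± 1, everything else `other_incorrect`.
Closed boundaries follow the reading of "included in the ± range" as a
closed interval. Under the defaults the three windows are disjoint, so
the classification is a partition (tested over a fine grid); if a user
supplies overlapping windows, precedence is
correct > sensitivity > specificity, because correctness must dominate
any confusion attribution.

**Prevalence is an input, not a constant.** The shipped example config
(`inst/extdata/covid_ppv_config.json`) uses sensitivity 0.90,
specificity 0.99 and prevalence 0.0039, which yields PPV 26.06% ≈ 26%
and renders as "36 of 40 diseased test positive" in a population of
10 256. Any other task is described by its own config.

**The confidence slider's direction.** The paired-VAS widget displays a
blue uncertainty zone of width 0.02·s² for slider setting s, yet is
described as growing when confidence shrinks — consistent only if the
slider encodes uncertainty. Rather than guess the original coding,
`blue_zone_width()` takes a `slider_encodes` argument
(`"confidence"`, the literal formula, is the default) and `clip`
controls whether the rendered width is capped at the axis span (the
stored value is always the raw formula output).

# Metacognition summaries

Discrimination is the per-participant difference
Δ = mean confidence (correct) − mean confidence (incorrect).
Participants with no correct or no incorrect answers have undefined Δ
and are excluded from Δ aggregation, with a message; this matters at
performance levels 0 and 12, which real cohorts populate thinly.
The calibration curve reports, per performance level k = 0..K, the mean
and SEM (sample sd / √n, n − 1 denominator) of per-participant mean
confidence on the probability scale, keeping empty levels with n = 0 so
the curve always spans the full performance range.

`classify_advanced()` encodes the advanced-statistics subgroup rule
(mathematics degree, PhD, or ≥ 20% research time).
`sqrt_conf_transform()` (y = √(100 − x)) is provided for callers who
model near-ceiling confidence with linear models; the package itself
fits no such model but `export_long()` writes the
participant-per-claim table a mixed-effects analysis needs (participant
as random intercept). Mixed-model fitting is deliberately out of scope.

# Synthetic respondents

The generator is *not* a model fitted to data; it is the minimal
standard model producing the phenomena the analysis must detect, so the
pipeline can be validated by parameter recovery.

## Claim exercises: signal detection with metacognitive noise

For participant i and claim j:

- ability θᵢ ~ N(0, `ability_sd`²), discriminability
  dᵢⱼ = max(0, δ₀ + θᵢ − bⱼ) with claim difficulty bⱼ;
- evidence eᵢⱼ ~ N(tⱼ dᵢⱼ/2, 1) with tⱼ = ±1 the claim's truth;
  the verdict is sign(eᵢⱼ), so P(correct) = Φ(dᵢⱼ/2);
- confidence reads the *same* evidence corrupted by post-decision noise
  ηᵢⱼ ~ N(0, σₘ²): conf = clamp(100·β·(2Φ(|eᵢⱼ + ηᵢⱼ|) − 1), 0, 100);
- the recorded VAS value is verdict × confidence.

β > 1 produces overconfidence; σₘ > 0 degrades discrimination without
touching accuracy, which is what makes "discrimination decreases in
σₘ" a recoverable, monotone signature (tested over σₘ ∈ {0, 1, 3}).

## Default parameters (the stated world)

Cohort sizes (522 students, 151 residents, 22 foreign, 203 physicians)
mirror a large French clinician survey. Twelve claims in two exercises
carry a difficulty gradient (−1.2 to 1.4) chosen once so per-claim
accuracy spreads widely; δ₀ = 0.8 and `ability_sd` = 0.8 put mean
accuracy near 60%; β = 1.3 and σₘ = 1 give a clearly overconfident
cohort with positive but imperfect discrimination. The PPV-task mixture
under conditional-probability framing (correct 0.08, sensitivity
confusion 0.41, specificity confusion 0.12, other 0.39) matches the
error structure reported for that framing, and natural-frequency
framing multiplies the correct weight by 2 before renormalisation
("twice as likely to be correct"). Confusion categories draw high
confidence (Beta(10,2), Beta(14,1) × 100), similar to or higher than
correct answers (Beta(12,2)), other errors lower (Beta(5,2)). These
values were fixed before the test suite was run and are not tuned.

## What the generator does not emulate

- **Below-chance claims.** Because P(correct) = Φ(d/2) ≥ ½, systematic
  misconceptions — claims real cohorts answer *below* chance — cannot
  occur. A green recovery test therefore says nothing about the
  pipeline's behaviour on below-chance items (the scoring itself is
  exercised on such patterns by direct fixtures instead).
- **Saturated low performers.** With the default β the calibration
  curve is high and fairly flat; real cohorts show lower confidence at
  the lowest performance levels than this generator produces.
- **Item content.** Claims are exchangeable given their difficulty;
  there is no trimodal easy/hard/intermediate typology.

## Reproducibility

One master seed; each participant gets a substream seeded by a stable
31-bit string hash of (tag, participant id), one stream for their claim
responses and an independent one for their PPV-task draw. Identical
config ⇒ byte-identical tables, and regenerating a subset of
participants reproduces their rows exactly. (The substream is per
participant rather than per participant × claim: the same
partial-regeneration property at the granularity that matters, with 12×
fewer seedings.) With σ = 0 R's `rnorm` still consumes one draw per
variate, so cohorts simulated at different σₘ share their evidence
draws — the σₘ comparison is paired by construction.

# Statistics conventions

All printed-statistic reproductions rest on two conventions: Yates'
continuity correction ON by default for 2×2 tables *and* for the
one-sample proportion test (the latter hand-rolled, since R's
goodness-of-fit chi-square has no correction), and exclusion of
unknown-gender records from gender tables. Contingency tests delegate
to `stats::chisq.test`; the test suite checks them against a
brute-force Σ(O−E)²/E oracle, and the Mann–Whitney p against exhaustive
enumeration of rank assignments at n ≤ 8. Expected cell counts below 5
warn but do not error, matching how such tables are analysed in
practice. Two published values (49.3 and 0.10) recompute to 49.354 and
0.1056 — evidently truncated rather than rounded at source — so the
acceptance tests assert agreement within one unit of the last printed
digit for those two, and printed-precision equality everywhere else.

# Pipeline guarantees

`validate_inputs()` drops missing responses row-by-row with logged
coordinates, hard-errors on out-of-range VAS values, unknown claim ids
and malformed framings, and excludes a participant from exactly those
exercises in which they answered nothing. `run_analysis()` is fully
deterministic (all randomness lives in the generator) and conserves
records: analyzed + dropped rows reconcile with the input, a property
the tests assert. The CLI (`simulate` / `analyze` / `report`) is a thin
wrapper over these functions with exit codes 0/1/2; configs are JSON.
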