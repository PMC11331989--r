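---
title: "Methods: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadarc)
```

## The paradigm and what the pipeline computes

`dyadarc` analyses face-to-face competitive reaction time sessions played by
romantic couples. Each of 30 rounds is a button-press race; the faster player
wins unless the two reaction times are within 100 ms of each other, in which
case the winner is drawn at random (partial rigging, keeping win rates near
0.5 without arousing suspicion). The winner selects the volume of a noxious
sound blast for the loser on a 1–8 scale (75–110 dB); blast level
operationalizes reactive aggression. Depending on the between-couples
condition the winner selects immediately or after a forced break of 5, 10 or
15 s, and may voluntarily wait longer (an elective break).

Both faces are video-coded by an automated FACS tool into per-frame action
unit (AU) intensities on a 0–5 scale. The pipeline converts these into
prototypic emotion intensities, positive = happiness and negative = anger or
disgust (the "moral emotions"), and summarises them in ±1 s windows around
two events per round: winner announcement (T1) and blast selection (T2).
Downstream stages then compute:

* **high-affect classification** — a trial is high-negative when its
  windowed negativity strictly exceeds the pooled mean + 1 SD;
* **compounding** — immediate-response trials are split by whether neither,
  only the loser, only the winner, or both partners were high-negative, and
  the headline contrast is the percent change in mean blast from *neither*
  to *both*;
* **win-streak compression** — consecutive same-winner rounds collapse to
  one interval carrying mean blast and mean negativity, yielding an
  alternating-winner series;
* **escalation/retaliation** — per-transition coefficients (own mean blast
  minus the partner's previous mean blast, a possible −7…+7), their
  match/escalate/de-escalate split, within-couple asymmetry, and blast
  matching correlations (grand-mean and lagged);
* **actor–partner interdependence (APIM)** — negativity at interval
  \(R_i\) regressed on one's own (`actor`) and the partner's (`partner`)
  negativity at \(R_{i-1}\), with role-specific intercepts and slopes and a
  couple-level random intercept;
* **mediation** — the forced-break effect on blast decomposed into a direct
  path and an indirect path through winner negativity at selection, with a
  couple-clustered percentile bootstrap for the indirect effect.

## The generative simulator: the stated world

`sim_config()` fixes one set of defaults and the package treats them as the
world the tests live in; they are not tuned per test.

| parameter | default | rationale |
|---|---|---|
| `n_rounds` | 30 | session length of the paradigm |
| `condition` weights | 23/32/23/26 | the primary study's allocation across immediate/5 s/10 s/15 s |
| `rig_window` | 100 ms | the paradigm's rigging rule |
| `rt_location`, `rt_scale` | log(300), 0.25 | lognormal reaction times around 300 ms, a typical simple-RT scale |
| `actor_effect`, `partner_effect` | 0.3, 0.15 | the magnitudes the immediate-condition APIM reports |
| `neg_baseline` | 0.26 | chosen so the stationary mean of the carry-over recursion, 0.26/(1 − 0.45) ≈ 0.47, sits at the printed winner-revealed negativity (≈ 0.48) |
| `decay_rate` | `calibrate_decay_rate()` ≈ 0.1163/s | solves 0.48 → 0.15 over a 10 s break (the printed forced-break T1/T2 means) |
| `neg_noise_sd` | 0.2 | matches the printed negativity SD (0.21); with Gaussian innovations ~16% of trials fall above mean + 1 SD, the printed high-negativity rate |
| `pos_baseline`, `pos_noise_sd` | 0.83, 0.7 | printed positive-affect mean/SD (0.83/0.77): affect is predominantly positive |
| `blast_baseline` | 1.4 | with matching weight 0.45 and the negativity weights, steady-state mean blast ≈ 3.6, near the printed 3.72 |
| `own_neg_weight` | 1.26 | the printed negativity→blast slope |
| `partner_neg_weight` | 1.0 | somewhat smaller than the intra-personal weight, consistent with the compounding ordering (winner-only above loser-only) |
| `match_weight` | 0.45 | reproduces lagged matching correlations of the observed order (~0.44) |
| `asymmetry_sd` | 0.75 | between-player spread of escalation tendency; induces the observed higher/lower-partner anticorrelation |
| `blast_noise_sd` | 1.8 | gives a blast SD ≈ 2.2–2.3, near the printed 2.31 |
| `elective_extra_rate` | 2 s (mean) | elective extra waits are reported to exist and vary but with no distribution; an exponential (memoryless) wait is the least-structured choice |
| `fps` | 30 | the video frame rate |

### Negativity dynamics operate on the interval series

The carry-over recursion
\[
N_i = \beta_0 + u_c + a\,N^{own}_{i-1} + p\,N^{partner}_{i-1} + \varepsilon_i,
\qquad \varepsilon_i \sim \mathcal N(0, \sigma^2),\ u_c \sim \mathcal N(0, \tau^2),
\]
advances once per *interval* of the alternating-winner series (i.e. whenever
the winner changes), not once per raw round: rounds inside a win streak
share the interval's value. This is a deliberate reading. The fitted APIM is
defined on the streak-compressed series, so a raw-round lag would be
attenuated by streak averaging and parameter recovery would not be
well-posed; with interval-level dynamics the generative model and the fitted
model coincide and the recovery tests are meaningful. The couple-level
intercept \(u_c\) (SD 0.05 by default) gives the fitted couple-level
variance component something real to estimate.

Negativity at T1 is the interval value; negativity at T2 is the T1 value
decayed exponentially over the forced plus elective break. Values are
clipped to the 0–5 intensity scale.

### Blast choice

The winner's blast is
`clip(round(gamma0 + match * partner_prev + w1 * neg_own + w2 * neg_partner
+ asymmetry + noise), 1, 8)`. Round-then-clip is the simplest lawful
discretization onto the 1–8 response grid. The configuration field
`blast_baseline` (γ₀) is needed for the rule to have a defined location; on
the very first selections, before the partner has blasted at all, the
matching term references the grid midpoint 4.5 (no information either way).
Two consequences worth knowing:

* clipping and rounding attenuate fitted regression slopes on blast when
  the blast distribution piles on a boundary — the mediation
  structure-recovery experiment therefore centres the scale
  (`blast_baseline = 3.5`) so the pattern, not the boundary, is tested;
* the midpoint reference creates a small first-interval transient in mean
  blast, which is well inside the noise of the escalation-over-time slope
  test.

### AU emission

Frames are emitted on a regular `fps` grid covering the session. Within a
±1 s epoch around T1 and T2, AUs 6 and 12 carry the positive intensity and
AUs 4, 9 and 23 carry the negative intensity; one noise draw per *channel*
per frame is shared by that channel's AUs, mimicking whole-display jitter
(the AUs of a display move together — and per-AU independent noise would
bias the max-combination negative score upward). All other AU columns of the
dialect carry pure half-normal noise so readers must be robust to irrelevant
channels. When T1 and T2 epochs overlap (immediate responses), the epoch
with the nearest centre wins frame by frame; the two event windows are still
computed independently downstream.

### What the simulator does *not* emulate

Green tests establish internal consistency, not ecological truth. Known
gaps: there is no feedback from received blasts to negativity, so the
condition difference in T1 negativity seen in real data (immediate ≈ 0.29
vs forced break ≈ 0.48) is not reproduced — the simulator holds T1 dynamics
common across conditions and differentiates conditions only through decay;
positive affect is white noise around a baseline rather than dynamic;
reaction times do not drift with fatigue; and no questionnaire structure
beyond uniform item sampling is modelled.

## Scoring and classification choices

* **AU sets.** Defaults: happiness {6, 12}, anger {4, 23}, disgust {9} —
  the named AUs of the composite-display analysis. The full EMFACS
  combination table lives in an unavailable supplement, so the sets are
  config-overridable (`au_rules()`, JSON-loadable).
* **Negative channel.** `max(anger, disgust)` by default: either moral
  emotion alone marks a display as negative; `mean` is available.
* **Within-emotion aggregation** is the mean of required AUs, keeping the
  0–5 scale (a sum would not).
* **Windows** are closed intervals with inclusive endpoints at frame
  resolution; a 2 s window at 30 fps contains 61 aligned frames. Empty
  windows are an explicit signal, never silently zero.
* **Threshold scope.** The high-affect threshold defaults to pooling all
  trials of all participants (the single-sample phrasing of the rule);
  a per-group scope is available since per-study or per-condition pooling
  cannot be ruled out. Sample (n−1) SD, strict `>`.
* **Match tolerance.** Streak means can be non-integer, so "match" defaults
  to exact equality of means with a documented `match_tol = 0.5` option
  treating sub-half-blast differences as matches; both readings of the
  published split are thereby preserved.

## Inference choices

* The APIM uses the two-intercept, role-stratified parameterization
  (separate winner/loser intercepts and slopes) with a couple random
  intercept, estimated by ML via `lme4`. Wald intervals are reported. For
  degenerate inputs (zero residual variance) the fixed structure is
  refitted by OLS — unidentifiable terms are reported as 0 with `NA`
  uncertainty — and the fallback is recorded in the diagnostics.
* Mediation paths are plain OLS, so the decomposition `c = c' + a·b` is
  exact on a common sample; inference on the indirect effect is a
  percentile bootstrap resampling whole couples (the CI method is otherwise
  unstated in the source analyses; clustering respects the dyadic
  dependence). Wald p-values are reported alongside for comparability.
* Rank tests use mid-ranks, tie-corrected variance and a 0.5 continuity
  correction; the exact mode enumerates all group assignments (valid under
  ties) up to a pooled n of 12. The effect size is \(r = |Z|/\sqrt N\).
* JZS Bayes factors integrate the Cauchy-mixed marginal likelihood by
  adaptive quadrature (relative tolerance 1e−8) with the conventional
  medium prior scale \(\sqrt 2 / 2\); regression mode uses the
  Zellner–Siow g-prior. No multiple-testing correction is applied anywhere,
  matching the source analyses.
* Trait aggression (BPAQ-SF) is the unweighted sum of 12 items on 1–5,
  range 12–60. The published sample mean (13.86) sits close to this floor;
  whether items were in practice coded 0–4 cannot be determined from the
  text, and the package keeps the documented 1–5 coding.

## Numerical and degenerate-input conventions

Configs are JSON (the one structured key-value format with a pre-installed
reader here). All times are seconds on the session clock; round indices are
1-based. Blasts outside 1–8 or intensities outside 0–5 are contract
violations, not warnings. A zero-SD threshold scope flags nothing; zero
variance makes correlations `NA` with an explicit degeneracy flag rather
than an error. Identical seeds reproduce byte-identical studies and
pipeline outputs.

## Verification scope

The acceptance suite covers in-paper arithmetic (the 86% compounding
contrast, decay calibration), analytic bounds (escalation coefficients over
the exhaustive 8×8 grid), exhaustive small-n enumeration for the exact rank
test, quadrature cross-checks for the Bayes factors, and simulation-based
recovery for the APIM (±0.05 at 200 couples, partner-null coverage) and the
mediation structure. Three published statistics (the 15/46/39 escalation
split, the 0.84/0.44 matching correlations, and the 16% high-negativity
rate) are recomputable only from the study's deposited dataset; the
corresponding tests run the computation when a local copy is placed under
`inst/extdata/zenodo-12936112/` and otherwise fail with an explanatory
message — deliberately red rather than skipped, because the quantities are
unverifiable offline.
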