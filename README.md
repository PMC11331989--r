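# dyadarc

Dyadic affect and aggression dynamics for face-to-face competitive reaction
time sessions.

## The problem

Reactive aggression between intimate partners is driven by negative
emotional arousal — one's own (*intra*-personal) and one's partner's
(*inter*-personal) — and by impulsivity. A lab paradigm that makes this
measurable has couples play a multi-round reaction-time game in which each
round's winner chooses the volume of a noxious sound blast (1–8, 75–110 dB)
delivered to the loser, while both faces are video-coded into facial action
unit (AU) intensities. Experimentally imposed **forced breaks** (5/10/15 s
between winning and being allowed to respond) test whether blocking
impulsive action while negativity decays reduces aggression.

`dyadarc` is a tested, reusable pipeline for this kind of study, aimed at
researchers analysing dyadic trial logs plus automated-FACS output. It
covers:

* **Emotion scoring** — per-frame prototypic emotions from AU intensities
  (positive = happiness {AU6, AU12}; negative = anger {AU4, AU23} or
  disgust {AU9}, combined by max), windowed ±1 s around winner announcement
  (T1) and blast selection (T2).
* **Trial features** — high-affect classification (value > mean + 1 SD,
  strict), compounding categories (neither / loser-only / winner-only /
  both partners high-negative), win-streak compression into an
  alternating-winner series, elective-break timing.
* **Dyadic dynamics** — escalation coefficients
  (own blast − partner's previous blast ∈ [−7, 7]) with
  match/escalate/de-escalate splits, within-couple asymmetry, and blast
  matching correlations (grand-mean and lagged).
* **Inferential models** — a two-intercept longitudinal actor–partner
  interdependence model (APIM),
  `neg_i ~ role + role:actor(neg_{i-1}) + role:partner(neg_{i-1}) + (1 | couple)`,
  and a forced-break mediation model of blast through winner negativity
  with a couple-clustered percentile bootstrap.
* **Statistical primitives** — rank-sum tests with continuity and tie
  corrections plus exact enumeration, effect size r = |Z|/√N, Cronbach's α,
  JZS (Cauchy-prior) Bayes factors, BPAQ-SF trait-aggression scoring.
* **A generative simulator** of whole sessions (rigged wins within a 100 ms
  window, negativity carry-over with actor/partner effects, exponential
  decay across breaks calibrated 0.48 → 0.15 over 10 s, retaliatory blast
  choice, AU frame emission) so the entire pipeline is exercisable with no
  external data and known ground truth.

## Worked example

```r
library(dyadarc)
study  <- simulate_study(sim_config(n_couples = 20, emit_au = FALSE), seed = 1)
result <- run_pipeline(study$trials, boot = 1000, seed = 1, quiet = TRUE)
print(result$summary)
```

```
Study summary
  blast (immediate):    mean 4.08 sd 2.37
  blast (forced break): mean 3.90 sd 1.95
  affect: positive 0.87, negative 0.15; high-negative trials 16.8%
  winner negativity T1 -> T2 (forced break): 0.47 -> 0.14
  compounding: neither 3.06, both 5.93 (+94%)
  escalation: match 12%, escalate 46%, de-escalate 42%
  matching: grand-mean r 0.56, lagged r 0.40, trend slope 0.00746
```

Reading this: affect is predominantly positive (0.87 vs 0.15) with ~16% of
trials classified high-negative; winner negativity decays from 0.47 at
announcement to 0.14 at selection across forced breaks; mean blast rises
from 3.06 when neither partner is high-negative to 5.93 when both are (a
+94% compounding contrast at this seed and sample size); partners escalate
on 46% of transitions and match each other's blasts (lagged r = 0.40) with
no time trend. The fitted models are in `result$apim` and
`result$mediation`:

```r
print(result$mediation)
```

```
Forced-break mediation through winner negativity
  total  c      =  -0.1870 (p = 0.492)
  a (break->neg)=  -0.1567 (p = 1.84e-22)
  b (neg->blast)=  -1.3485 (p = 0.0612)
  direct c'     =  -0.3983 [-1.9791, 1.1027]
  indirect a*b  =   0.2113 [-0.1669, 0.5572] (875 bootstrap resamples)
```

(Breaks strongly reduce negativity — the a path; at 20 couples the b path
and indirect effect are not resolved, which is why the recovery tests use
80–200 couples.)

A command-line interface wraps the same stages:

```sh
dyadarc simulate --out sim_out --seed 7
dyadarc run --trials sim_out/trials.csv --out results_dir --seed 7 --boot 1000
```

## Layout

```
R/                 implementation (simulator, scoring, features, dynamics,
                   models, stats primitives, pipeline, CLI)
exec/dyadarc       command-line entry point
tests/testthat/    unit + property tests and test-acceptance.R
scripts/acceptance.R
vignettes/dyadarc-methods.Rmd   the methods vignette (models, calibration,
                                design choices, limitations)
```
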