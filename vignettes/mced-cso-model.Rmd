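---
title: "Modeling the benefit of CSO prediction in MCED screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the benefit of CSO prediction in MCED screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcedcso)
```

## The model

A multi-cancer early detection (MCED) blood test has two outputs: a binary
cancer-signal detection with a single aggregate false-positive rate, and —
when a signal is detected — a predicted cancer signal origin (CSO) that
directs the diagnostic workup. `mcedcso` models the chain from stratified
cancer incidence to diagnostic-chain yield and lives saved, one population
stratum (sex, 5-year age band, smoking status) at a time.

### Interception and stage shift

Cancer natural history is a forward progression through stages I–IV. A
cancer destined for clinical diagnosis at stage $s_\mathrm{clin}$ spends an
exponential sojourn with mean $d_j$ years in each earlier stage $j$, and an
exponential residence with mean $d_{s_\mathrm{clin}}$ in its clinical stage
before diagnosis. Screens arrive every $T$ years (default 1) with uniform
random phase, so a screen falls inside stage $j$ with probability

$$q_j = \min\left\{1, \frac{d_j}{T}\left(1 - e^{-T/d_j}\right)\right\},$$

which is exact for a single stage (the stage is missed exactly when its
duration is shorter than the uniformly distributed time to the next
screen).

Detectability is trajectory-based: a cancer starts shedding detectable
signal at some onset stage and keeps shedding afterwards. The observed
per-stage sensitivities are therefore read as the cumulative fraction of
cancers already shedding by each stage. Raw estimates can dip with stage
from sampling noise, so they are first enveloped by their running maximum
$\hat{s}_j = \max_{k \le j} s_k$; the onset weight for stage $j$ is
$\hat{s}_j - \hat{s}_{j-1}$ and $1 - \hat{s}_{IV}$ of cancers are never
detectable. We use the running maximum rather than a least-squares isotonic
fit because the cumulative-onset reading makes the envelope, not the
projection, the quantity of interest; for monotone inputs the two coincide.

A cancer with onset $b \le s_\mathrm{clin}$ is intercepted at the first
stage $j \ge b$ whose screen capture succeeds, with per-stage captures
treated as independent:
$P(\text{intercept at } j \mid b) = q_j \prod_{k=b}^{j-1}(1-q_k)$.
Mass never captured by the end of the clinical stage is an interval or
usual-care diagnosis. Same-stage detection
($s_\mathrm{det} = s_\mathrm{clin}$) counts as screen-detected but earns no
survival benefit. Unstaged incidence is carried through (detected with
probability $\hat{s}_{IV} \, q_{IV}$) but never stage-shifted. Expected
false positives are `fp_rate` times the cohort minus the expected
screen-detected cancers; the difference from `fp_rate × cohort` is below
1% in every configuration shipped.

The **prevalence** (first-screen) round detects the standing preclinical
pool instead: the pool in stage $s$ from cancers headed for clinical stage
$s_\mathrm{clin} \ge s$ is length-biased, incidence flow times $d_s$, and
is detected at its current stage with probability $\hat{s}_s$. Case
conservation for this round is therefore stated against the pool, not
against annual incidence (the incidence-round conservation law
`detected + not_detected = incident cases` holds to 1e-9 relative and is
asserted in the tests).

### The independence approximation, quantified

Treating per-stage captures as independent is an approximation to a single
phased screen stream: in reality, missing a stage changes the phase at
which the next stage is screened. The package's Monte-Carlo cohort
simulator (`simulate()`) supports both regimes — `mode = "independent"`
realizes exactly the analytic assumption (agreement there is pure
Monte-Carlo noise and validates the closed forms), while `mode = "shared"`
uses one phased stream per person, the physically faithful process.
Replicated comparison on the synthetic study conditions puts the
approximation bias at about 2% of total detections and up to roughly 8% of
individual stage- or class-level cells (the analytic model slightly
undercounts later-stage interceptions). The acceptance suite bounds the
shared-stream discrepancy by 3 Monte-Carlo standard errors plus a
configured allowance of 3% on totals and 10% on cells; the independent-mode
comparison carries no allowance.

### CSO assignment

Given the clinical CSO $c$ of a detected cancer, the predicted CSO follows
the validation-study confusion row smoothed by a reference prior $\pi$
(the clinical-CSO frequencies among signal-detected training cases):

$$p(o \mid c) = \frac{n(c,o) + \alpha\,\pi(o)}{\sum_{o'} n(c,o') + \alpha}.$$

The default prior weight is $\alpha = 1$ total pseudo-count per row —
enough to make every probability strictly positive (finite validation sets
cannot exclude rare misassignments) while moving observed rows negligibly;
its influence is exposed to the uncertainty machinery. False positives
receive the analogous smoothed distribution built from the few observed FP
predictions. Classes mapping to no CSO (a residual "other" group) use a
dedicated confusion row when one is supplied, otherwise the prior itself.
Predictions are deliberately not sex-restricted — a male can receive a
breast prediction — while anatomically impossible clinical cancers are
excluded upstream by the registry's sex restrictions.

### Diagnostic chain and outcomes

Each predicted-CSO pool holds $A$ expected true positives of any type, $M$
of the matched type, and $F$ false positives. The CSO-directed first step
is modeled as 100% sensitive for the matched type and 0% for others, so

$$\mathrm{PPV}_\mathrm{any} = \frac{A}{A+F},\quad
  \mathrm{PPV}_\mathrm{first} = \frac{M}{A+F},\quad
  \mathrm{PPV}_\mathrm{remaining} = \frac{A-M}{(A-M)+F},$$

with false positives persisting until a general test resolves them. Empty
pools yield flagged `NA`s, never silent zeros. Per-CSO pass/fail is
reported against a configurable 7% workup threshold, compared inclusively.

Lives saved are 5-year-survival increments: an interception from
counterfactual stage $s_\mathrm{clin}$ to $s_\mathrm{det}$ contributes
$s5(c, s_\mathrm{det}) - s5(c, s_\mathrm{clin})$, clamped at zero when
registry noise makes stage-specific survival non-monotone (a warning is
emitted at table construction). No discounting and no life-years — the
metric is the expected increment in 5-year survivors. Matched detections
accrue to the directed step, cross-talk detections to the later general
step. Tests per life saved divide the pool (every entrant consumes one
directed test; everyone but the matched true positives consumes one
general test) by those lives, benchmarked against 240 diagnostic
mammograms per life saved. Classes without stage-resolved survival are
excluded with a flag; CSOs are excluded from cross-CSO medians when no
mapped class has detectable signal, the confusion diagonal is zero, or
survival is missing — the summaries always report the inclusion set.

Two sensitivity variants reduce (never increase) the lives-saved metric:

- **Competing risks**: each increment is multiplied by the age band's
  5-year all-cause survival.
- **Hazard ratio**: ctDNA-detectable cancers are postulated to have a
  proportional-hazards penalty $h > 1$ while preserving the observed
  mixture survival; on the 5-year scale $s_\mathrm{det} = s^{hk}$,
  $s_\mathrm{non} = s^k$ with $k$ solving
  $f s^{hk} + (1-f) s^k = s$ (bisection via `uniroot`, tolerance 1e-12),
  where $f$ is the per-stage detectable fraction (the sensitivity
  envelope). The screen-detected arm uses the detectable-subgroup survival
  at the detected stage while the counterfactual arm keeps the observed
  stage-specific survival. Applying the subgroup survival to *both* arms
  can widen the survival gap and increase lives saved — the opposite of
  the variant's intent of discounting benefit for biologically aggressive,
  shedding tumors — so the asymmetric form, which is guaranteed
  non-increasing, is used.

### Smoking adjustment

Registry incidence carries no smoking stratification, so the package
recovers a class baseline from the observed mixture,
$\mathrm{baseline} = \mathrm{rate}_{any} / \sum_k w_k RR_k$, and scales by
the target status's relative risk. This is the unique normalization under
which the population mixture reconstitutes the unadjusted rates exactly
(asserted to 1e-9), and `any` is the identity. Classes without a published
relative risk default to $RR = 1$ and are reported. Population fractions
$w$ are a required input; the synthetic generator's default is 55% never /
30% former / 15% current.

### Uncertainty propagation

Posterior draws use conjugate forms with Jeffreys priors:
$\mathrm{Beta}(x + \tfrac12, n - x + \tfrac12)$ for each per-class
per-stage sensitivity and for the FP rate, and
$\mathrm{Dirichlet}(n(c,\cdot) + \alpha\pi)$ for confusion rows and the FP
CSO distribution. Each draw re-runs the full pipeline; summaries report
the point estimate, the draw median, and 2.5%/97.5% draw quantiles. With
realistically sparse FP counts the FP-CSO Dirichlet is heavily skewed, so
draw distributions need not center on the point estimate — the draw median
is reported precisely so the quantile ordering `lo <= central <= hi` is
structural. Variance attribution resamples one input block at a time
(sensitivities, FP rate, confusion) with the others at point estimates —
cheaper than Sobol indices and sufficient to rank drivers. Failed draws
are skipped with a logged cause and counted.

### Workup strategies

Three strategies over the same positive pool: directed-then-general (all
true positives found), directed-only (workup stops after the first step;
cross-talk cancers remain undiagnosed with residual risk equal to the
pooled $\mathrm{PPV}_\mathrm{remaining}$, also emitted per CSO), and
general-only. Under the 100%-sensitivity chain assumption,
$\mathrm{lives}(\text{directed-only}) \le \mathrm{lives}(\text{A}) =
\mathrm{lives}(\text{general-only})$ exactly. The expense break-even ratio
$r^* = \mathrm{directed}_A / (\mathrm{general}_C - \mathrm{general}_A)$ is
the general:directed cost ratio at which the directed-then-general and
general-only strategies tie; "expense" is an abstract test-count ratio,
not currency.

## The synthetic study conditions

`generate_synthetic_inputs()` defines the study conditions with known
ground truth. Its defaults are fixed once and emulate the structure — not
the numerical marginals — of registry and validation-study inputs:

- class-level incidence spans three orders of magnitude, rescaled so the
  all-site total is about 1,200 per 100,000 person-years before age
  factors (≈1.8% annual incidence for women aged 65–69, a plausible
  screening-age scale), with a ×1.5-per-decade age gradient and an
  unstaged share of 2–8%;
- one class is lung-like (smoking relative risks 1/4/10 for
  never/former/current), the others mild;
- sensitivities rise with stage; one class sheds nothing at any stage and
  one clinical CSO is never predicted correctly, so the modelability flags
  are always exercised;
- dwell means are 2, 1, 1, 0.5 years for stages I–IV (fast-aggressive =
  half of each) — placeholders on the scale used in interception modeling,
  not calibrated values;
- the confusion matrix is diagonal-dominant to a difficulty-dependent
  degree (`easy` = identity with no false positives, `realistic` ≈
  30-count diagonals with Poisson(1.5) off-diagonals and FP rate 0.5%,
  `adversarial` = weaker diagonals, FP rate 1%, 25% faster dwell);
- 5-year survival decreases with stage; one class lacks survival entirely
  in the non-easy difficulties.

Unit tests use 8 classes and 6 CSOs; the full-shape demo and the
acceptance script use 26 classes and 21 CSOs. What passing tests show is
that the analytic pipeline integrates *this* generative process correctly
(verified against the individual-level simulator) and that every
conservation law and directional claim holds on it; they cannot show that
real registry incidence, real dwell times, or a real classifier's
confusion structure are well represented.

## Numerical choices and degenerate inputs

- Capture probabilities use `expm1` to avoid cancellation at long dwell
  times; conservation residuals sit at machine precision (~1e-16).
- Empty pools, zero lives saved, and a vanishing break-even denominator
  all yield flagged `NA`s rather than zeros or infinities.
- Medians over an even number of CSOs are the mean of the central pair;
  threshold comparisons are inclusive.
- The generator rounds emitted rates to 6 decimals *before* computing
  ground truth, so file round-trips reproduce stored truth to 1e-9.
- Problem sizes: Monte-Carlo oracle checks run 2×10^5 persons per
  comparison (per-class expectations of ~10–500 detections); uncertainty
  propagation defaults to 500 draws (200 in the acceptance script, 80–120
  in tests); the posterior coverage check uses 12 replicated synthetic
  validation studies with a binomial allowance (≥8/12 covered).

## Known limitations

- Diagnostic tests downstream of the screen are assumed perfectly
  sensitive for their target and harmless; no overdiagnosis, procedure
  mortality, or incidental findings.
- One incidence round and one prevalence round; no multi-year repeat
  screening accumulation, and the cohort simulator realizes the incidence
  round only (the prevalence round is a closed-form length-biased product
  checked by hand-computable cases).
- Second-best CSO predictions are not modeled; neither is retesting with
  the MCED assay as a resolution pathway.
- The hazard-ratio variant's magnitude and the dwell-time values are
  scenario parameters, not estimates.
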