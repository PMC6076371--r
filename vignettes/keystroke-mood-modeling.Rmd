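---
title: "Modelling mood severity from smartphone keystroke dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mood severity from smartphone keystroke dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

People with bipolar disorder cycle through depressive and manic episodes whose
onset is hard to catch between clinic visits. Passive smartphone typing
metadata — when keys were pressed and whether they were ordinary characters,
spaces, or backspaces, with the typed content itself discarded — is a dense,
unobtrusive behavioural signal. keymood implements a complete pipeline from
three raw streams to fitted severity models:

1. **Keypress events**: `subject_id`, millisecond timestamp with the subject's
   local UTC offset, and an event class (`REGULAR`, `SPACE`, `BACKSPACE`, or
   the software-generated `AUTOCORRECT`).
2. **Accelerometer samples**: displacement triples (x, y, z, m/s²) captured
   from each keystroke for the following 5 seconds (each new keystroke
   restarts the window), a proxy for psychomotor agitation.
3. **Weekly clinician ratings**: HDRS-17 (depression, 0–52) and YMRS (mania,
   0–60), one per subject, scale, and calendar week.

## The seven weekly predictors

For each assessment, features are computed on the half-open window
`(assessed_at − 7 days, assessed_at]`:

| predictor | definition |
|---|---|
| `avg_interkey_delay` | mean gap (s) between consecutive keypresses *within* sessions |
| `backspace_ratio` | backspace keypresses / all keypresses |
| `autocorrect_rate` | autocorrect events / all keypresses |
| `circadian_similarity` | cosine between the week's 24-hour keypress profile and the subject's whole-study profile |
| `avg_accel_displacement` | mean of per-sample magnitudes sqrt(x² + y² + z²) |
| `avg_session_length` | mean session length (s), last minus first keypress |
| `session_count` | number of typing sessions in the window |

A **session** is a maximal run of keypresses with every consecutive gap below
5 s; a gap of exactly 5 s splits (the threshold is ≥). Conventions worth
making explicit, because the definitions do not force them:

- Interkey delays are pooled **within sessions only**. Including the ≥ 5 s
  inter-session gaps would push the average delay far above the sub-second
  values typical of real typing; the session definition makes 5 s the natural
  censoring point.
- Session length is last-minus-first keypress (no 5-s tail); a
  single-keypress session has length 0.
- `AUTOCORRECT` events are software events, not presses: they never start or
  extend a session, never enter delays, and are excluded from the denominator
  of both ratios. An autocorrect rate above 1 is therefore possible in
  principle; it is flagged with a warning, never clipped.
- The circadian baseline pools the subject's **entire** study period,
  including the week being scored. Hour binning uses the UTC offset recorded
  on each event; there is no daylight-saving normalisation.
- Rows with no keypresses keep `session_count = 0` and missing values for
  every keypress-derived feature; downstream models drop them by pairwise
  deletion (a row is lost only to a model that needs one of its missing
  variables).

## The severity models

Predictors are standardized to pooled mean 0, SD 1 over the retained
observations, so coefficients are in outcome units per predictor SD. The
depression outcome is the raw HDRS-17 score; the mania outcome is
ln(YMRS + 1), which removes the right skew of YMRS scores (the package's
`sample_skewness()` implements the bias-corrected G1 coefficient used to
judge that skew).

The primary model is a random-intercept linear mixed-effects model fitted by
**maximum likelihood** (lme4, `REML = FALSE`):

y_ij = β₀ + Σ_k β_k x_ijk + u_i + ε_ij,  u_i ~ N(0, σ_u²), ε_ij ~ N(0, σ_ε²)

ML rather than REML is deliberate: the overall significance test is a
likelihood-ratio test between models differing in *fixed* effects (null =
intercept + subject effect; full adds the seven features, χ² with 7 df), and
the mixed-vs-OLS information-criterion comparison is only coherent under ML
with parameter counts k = p + 1 + 2 (mixed) versus k = p + 1 + 1 (OLS).
With those counts, AIC = 2k − 2ll and BIC = k ln(n) − 2ll reproduce the
published comparison in which both models share a log-likelihood at the
boundary and AIC favours OLS by exactly 2.

When the ML estimate of σ_u² lands on the zero boundary — every subject's
mood level explained without a subject effect — the mixed model is
degenerate and `fit_mood_model(..., model = "auto")` refits by OLS and
selects it, reporting both. At that boundary the two fits have identical
log-likelihoods and fixed effects, which the test suite asserts to 1e-4.

Reported statistics:

- **Wald chi-square tests** per coefficient: (β̂/SE)² against χ²₁, with
  normal 95% CIs β̂ ± 1.96 SE (both model families, matching symmetric
  published intervals). No multiplicity correction is applied across the
  seven tests, mirroring standard practice for this design; the count of
  tests is visible in the output.
- **Nakagawa–Schielzeth R²**: σ_f² is the population variance (divide by n)
  of the fixed-effects linear predictor; marginal R² = σ_f²/(σ_f² + σ_u² +
  σ_ε²), conditional adds σ_u² to the numerator.
- OLS: multiple and adjusted R², RMSE = sqrt(RSS/n), residual standard error
  with n − p − 1 df, overall F with (p, n − p − 1) df, coefficient t tests.
- `spearman_total_keys()` implements the Spearman check of total key counts
  against demographics via the S = Σd² statistic with midranks, because
  published S values for n = 9 are non-integer (a midrank signature).

## The synthetic cohort

No subject-level data are distributed with studies of this kind, so the
generator is a first-class module: it states a world with known ground truth
at the published scale — 9 subjects, 8 weeks, ≈ 9,800 keypresses and ≈ 10⁵
accelerometer readings per subject-week — against which the entire pipeline
can be validated end to end.

Per subject-week, a latent standard-normal mood-disturbance score z
modulates the generation channels through link slopes (log scale for rates
and delays, logit for probabilities): more disturbance means slower, more
erratic typing, more backspaces and autocorrects, larger device motion, and
a flatter diurnal profile. Streams are then realized:

1. Session count ~ Poisson(7 × `sessions_per_day_mean`), with session start
   hours drawn from a 24-hour circadian profile (mixed toward uniform by the
   disruption weight) and mean-preserving lognormal rate modulation, so the
   closed-form weekly mean `sessions_per_day_mean × 7 ×
   keypresses_per_session_mean` holds exactly.
2. Keypresses per session ~ 1 + Poisson(m − 1); interkey delays are
   lognormal, truncated below 5 s by inverse-CDF sampling so sessions never
   self-split by construction.
3. Key classes: backspace with `backspace_prob`, else space/regular; an
   independent autocorrect event with `autocorrect_prob`, co-located with
   its keypress.
4. Accelerometer: sampling runs from each keypress until the next keypress
   or +5 s — each keystroke *restarts* the one physical sensor's 5-s
   window, so only a session's final keystroke carries the full tail. A
   full 5-s window per keypress would multiply weekly volume five-fold past
   the stated ~10⁵ scale. Sample vectors are gravity times a random unit
   direction plus isotropic N(0, sd) component noise whose sd is scaled by
   the latent agitation term; larger agitation inflates the mean magnitude
   quadratically (≈ sd²/g above gravity).
5. The weekly features realized in the streams are extracted with the same
   code the analysis uses, standardized, and scores are drawn as
   `intercept + Σ β_k x_k(scaled) + u_i + ε`, then rounded and clipped to
   the scale range (HDRS on the raw scale; YMRS generated on the log scale
   and back-transformed before rounding).

Default outcome coefficients are the published fitted models themselves
(both scales), with variance components derived from the published variance
shares: σ_u ≈ 2.95 and σ_ε ≈ 3.83 for HDRS, σ_u = 0 and σ_ε ≈ 0.66 for
log-YMRS. Two generator choices deserve justification:

- **Per-feature jitter** (`feature_jitter_sd = 0.25`): at realistic stream
  volumes the weekly aggregates have negligible sampling noise, so features
  driven by a single shared latent score would be nearly collinear and the
  regression design singular. Independent per-channel-week variation keeps
  between-feature correlations moderate, which is also what real feature
  tables look like.
- **Degenerate features during generation** (e.g. `backspace_prob = 0`
  makes `backspace_ratio` constant) are centred to zero rather than
  rejected, contributing only through the intercept. The analysis-side
  `scale_predictors()` still refuses zero-variance predictors, naming them.

Weeks whose simulated stream contains no keypresses are emitted without an
assessment row (the subject skipped the rating) rather than with an invalid
missing score; at default volumes this never occurs.

Seeding is hierarchical: each subject's stream comes from a substream seed
derived from (seed, subject index), so enlarging the cohort does not perturb
existing subjects' streams.

### What the generator does and does not emulate

It reproduces the volume statistics, the session/delay/ratio structure, the
diurnal profile, the accelerometer magnitude scale, and a mood-linked
feature structure with known coefficients. It does **not** emulate typed
content, app context, autocorrelated mood trajectories (latent scores are
independent across weeks), missing-not-at-random adherence patterns, or
device-specific sensor noise. A green recovery test therefore establishes
that the pipeline is faithful to its own model, not that the published
effect sizes generalise.

## Validation strategy and known limitations

- **Sessionization** is checked against an independent brute-force splitter
  on a thousand random streams, plus keypress-count conservation.
- **Parameter recovery** (200 replicates) and **LRT calibration** (500
  replicates) run the 9 × 8 design at reduced per-week stream volume to fit
  a single-CPU budget; the week-level regression those checks exercise does
  not depend on stream volume. Two caveats are measured and documented
  rather than hidden:
  - Rounding and clipping scores to the scale floor censors roughly 5–10%
    of generated HDRS outcomes at 0, attenuating the largest positive
    coefficients by ≈ 0.1–0.2 outcome units — visible as bias in the
    recovery report. Disabling rounding (`round_scores = FALSE`) removes it.
  - The 7-df ML likelihood-ratio test is mildly anticonservative at n = 72
    (rejection ≈ 0.08–0.09 at nominal 0.05), a classic small-sample ML
    phenomenon that shrinks toward nominal as the cohort grows.
- **Hour-profile flatness** under a uniform circadian profile is tested on
  session start hours, the independent sampling unit; raw keypress counts
  are cluster-correlated within sessions and would overdisperse a naive
  chi-square.
- Timestamps are serialized at millisecond precision (the stated resolution
  of the capture layer), so a write/read cycle reproduces features to that
  resolution, not bit-for-bit; epoch-scale double arithmetic is accurate to
  ~10⁻⁷ s.
- Pipeline configuration files are JSON; no YAML parser is available in the
  supported dependency set.

## Reproducing a full run

```{r, eval = FALSE}
library(keymood)

cfg <- pipeline_config(
  out_dir = "run1",
  simulation = simulation_config(seed = 1),
  outcomes = c("hdrs17", "ymrs"),
  model = "auto",
  seed = 1
)
manifest <- run_pipeline(cfg)
```

This writes the three streams, `truth.json`, `features.csv`, a
variable-summary table, per-outcome fit reports, and a manifest with an md5
digest per artifact; reruns with the same seed reproduce the digests.
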