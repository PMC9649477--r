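---
title: "Methods: asymmetry-index diagnostics for early PD vs CBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: asymmetry-index diagnostics for early PD vs CBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Two lateralised markers discriminate early Parkinson's disease (PD) from
corticobasal syndrome (CBS).  The R2 blink-reflex recovery cycle (R2BRRC)
measures brainstem excitability: after paired supraorbital stimulation at an
interstimulus interval (ISI), the recovery ratio is the percentage ratio of
the conditioned to the unconditioned R2 peak-to-peak amplitude.  In early PD
the recovery at short ISIs is enhanced when the clinically less affected
side (LAS) is stimulated relative to the more affected side (MAS); CBS
recovers symmetrically.  Structural MRI inverts the pattern: CBS atrophies
the hemisphere contralateral to the MAS, PD does not.  Both are summarised
by the absolute asymmetry index

$$AI = \frac{|s_1 - s_2|}{s_1 + s_2} \in [0, 1],$$

where the two sides are the MAS- and LAS-stimulation recovery ratios at one
ISI (AI of R2BRRC) or the grey-matter metrics of the hemispheres
contralateral to the MAS and LAS (AI of MRI).  `dx_fit()` fits one
empirical-ROC classifier per index, evaluates published or Youden-optimal
cutoffs with exact binomial confidence intervals, and combines the two
indices into one classifier.

AI of R2BRRC is carried per ISI for 100, 150 and 200 ms — the short ISIs
where the group difference concentrates — and ISI 100 ms is the default
classification feature: its published group summaries (0.86 ± 0.36 in PD vs
0.10 ± 0.32 in CBS) reproduce the published discrimination through the
binormal bridge (below), which the other ISIs do not match as closely.  The
ISI is configurable (`pipeline_config(classification = list(isi = ...))`).

AI of MRI operates by default on hemispheric grey-matter *volume* (the
quantity published in mm³); mean cortical thickness is accepted as an
alternative via `mri_ai(..., metric = "thickness")`.  The published
description is ambiguous between the two ("cortical thickness volume"), so
both are supported and neither is asserted as the original quantity.

## Extraction choices

* **R2 window**: 27–87 ms after the (test) stimulus, the conventional
  blink-reflex R2 latency range; no window is published for this analysis,
  so it is a configurable default (`response_window()`).
* **Conditioned R2** is measured relative to the *test* (second) stimulus
  onset.  At short ISIs the window can open before late conditioning-
  response activity has fully decayed; this overlap is accepted, as in
  clinical practice, and flagged in the curve's `window_overlap` field.
* **Trials policy**: amplitudes are averaged across trials *before* the
  ratio is taken (`mean_amplitude`).  The ratio of mean amplitudes is
  stable when single conditioned responses are near zero, whereas a mean of
  per-trial ratios inherits their noise floor.  `mean_ratio` is available
  for comparison.
* **No filtering or rectification** is applied beyond raw peak-to-peak:
  recording-chain filters (20 Hz–10 kHz) are treated as properties of the
  input data.  A consequence discussed below: peak-to-peak under additive
  noise is positively biased, most visibly for near-zero responses.

## Diagnostics

The empirical ROC treats tied scores as one threshold step; its trapezoidal
area equals the Mann–Whitney concordance statistic (tested exhaustively for
n ≤ 30).  The Youden cutoff maximises J = sensitivity + specificity − 1
over observed thresholds, reported as the midpoint between adjacent
distinct scores; among ties in J the higher-specificity threshold wins.
Decisions at a cutoff use strict `>` ("greater than the cutoff"), matching
the published rule statement.  Confidence intervals are exact
Clopper–Pearson (Beta-quantile form): this method reproduces every
published interval pair to the printed decimal — (57.2, 98.2) for 12/14,
(55.5, 99.7) for 9/10, (34.8, 93.3) for 7/10 — which Wald and Wilson
intervals do not, so it is the package default and the assumed original
method.  The binormal AUC
$\Phi(|\mu_+-\mu_-|/\sqrt{\sigma_+^2+\sigma_-^2})$ bridges published group
summaries to discrimination where per-patient scores are unavailable;
applied to the ISI-100 summaries it gives 0.9427 → 0.94.

**Combining the two indices.**  How the two AIs were originally combined is
not specified, so two modes are implemented side by side.  The default,
`logistic_score`, fits a logistic regression of diagnosis on both indices
and classifies on the fitted score — the practice of standard ROC software.
The alternative, `sequential_rule`, is a transparent decision tree on the
two published cutoffs: call PD when AI of R2BRRC > 0.75, otherwise call CBS
when AI of MRI > 0.014, otherwise call PD (the doubly-negative cell, which
in the published cohort contains only PD patients... see the caveat below).

One structural point decided the default.  The published confusion
structure — 12/14 PD and 1/10 CBS above the blink-reflex cutoff, 7/10 CBS
and 2/14 PD above the MRI cutoff, and a perfect combined classifier — is
*impossible* for any rule built from the two cutoffs alone: those counts
force the (below, below) quadrant to contain patients of both groups, so
every cutoff-quadrant rule misclassifies someone.  A *fitted* score has no
such constraint, and the packaged fixture cohort is hand-placed to be
linearly separable in the two-AI plane, so the logistic score attains
AUC 1.0 and 100%/100% while the sequential rule tops out at 100%/60%.
This is why `logistic_score` is the default combination mode.

On a separable cohort the logistic likelihood has no finite maximiser;
`combined_classify()` detects this (fitted probabilities polarised to 0/1
by class), flags it, and keeps the boundary fit's linear predictor as the
combined score — the iteration stops at a direction that already ranks the
classes perfectly, so the ROC of the score is valid even though Wald
inference is not.  The same separation detection guards
`fit_logistic_adjusted()`, the age-adjusted association model; there, a
separation flag means "do not report these p-values".  Aliased predictors
(e.g. constants) are dropped from its coefficient table.

## The synthetic cohort generator

The generator emulates the published study conditions: two groups
(PD n = 14, CBS n = 10) with the published demographic summaries (age
64.6 ± 7.5 vs 71.1 ± 5.9 y; disease duration 1.7 ± 1.3 vs 2.9 ± 1.4 y;
UPDRS-ME 24.8 ± 11.8 vs 37.6 ± 15.2; H&Y 1.9 ± 0.3 vs 2.1 ± 0.5; 50% vs
40% male), asymmetry-index summaries (ISI 100: 0.86 ± 0.36 vs 0.10 ± 0.32;
ISI 150: 0.81 ± 0.37 vs 0.10 ± 0.32; ISI 200: 0.42 ± 0.36 vs 0.04 ± 0.10;
AI of MRI 0.006 ± 0.005 vs 0.02 ± 0.02) and total grey matter
(402,387 ± 28,257 vs 346,242 ± 24,986 mm³).  Design choices:

* **Truncation.**  The published means ± SDs imply substantial mass outside
  the valid ranges (e.g. 35% of N(0.86, 0.36²) lies above 1), so indices
  are drawn from normals truncated to [0, 1] and positive quantities
  truncated at 0 (inverse-CDF sampling; `rtruncnorm()`).  Truncation shifts
  the mean: the analytic truncated mean (`truncnorm_mean()`) is the oracle
  the tests and the acceptance script check recovery against, not the raw
  published mean.  H&Y stages are rounded to the clinical half-step grid.
* **Proportions as printed.**  The published counts and percentages for
  right-sided clinical onset disagree (7 of 14 printed as 50%, 7 of 10 as
  70%); the generator follows the percentages (0.50, 0.70) as sampling
  proportions.
* **Hemispheric volumes.**  Drawing total grey matter and the MAS-side
  hemispheric volume independently would give the implied AI of MRI an SD
  near 0.07 — an order of magnitude wider than the published 0.005/0.02,
  because the real quantities are strongly correlated within patient.
  Since AI of MRI is what the classifier consumes, the generator draws
  total volume and the AI, then sets the hemisphere pair to
  total·(1 ∓ AI)/2 with the atrophic hemisphere contralateral to the MAS.
  This preserves the published total-volume and AI marginals exactly and
  the MAS-hemisphere marginal to within ~1%.
* **Recovery profiles (trace mode).**  The baseline recovery cycle is a
  monotone saturating curve (5, 12, 30, 55, 75, 90, 100% at ISIs
  100–750 ms).  At the short ISIs the drawn asymmetry target $a$ is
  converted to a side pair (midlevel·(1 + a), midlevel·(1 − a)) with
  midlevels 30/30/35% — so the programmed pair has asymmetry exactly $a$ —
  and the elevated side is LAS stimulation for PD (the published pattern)
  or a coin flip for CBS.  No numeric recovery-curve values are published;
  these are package conventions, configurable in `cohort_config()`.
* **Waveforms.**  Each sweep holds a compactly-supported stimulus artifact,
  a small R1 complex (8–16 ms), and the R2 complex as a damped 60 Hz
  sinusoid supported exactly on the 27–87 ms window, rescaled so its
  sampled peak-to-peak equals the programmed amplitude
  (200 µV unconditioned) before additive Gaussian noise (2 µV default,
  a realistic surface-EMG baseline).  Sampling rate 5 kHz.  Compact
  support is what makes the noise-free round trip *exact*: extraction
  recovers the programmed ratios to machine precision, which the tests
  assert.
* **Trials.**  The number of trials per ISI is not published; the default
  is 5 conditioned sweeps per ISI and 2 unconditioned per side, declared
  in the config.

**Round-trip tolerances.**  With default noise and 10 trials, extracted
ratios stay within ±5 percentage points of their programmed targets.  Two
effects propagate into the re-extracted asymmetry index: the ratio error
itself, and a noise floor — max − min over the window cannot fall below
the expected span of window noise (~3.5 points here), so a fully
suppressed response is extracted as small-but-positive and an index near 1
shrinks by roughly 2·3.5/(2·30) ≈ 0.1.  The config therefore declares
`ai_tolerance = 0.2` for the per-patient round trip.  The bias is a
property of uncorrected peak-to-peak extraction — real recordings have it
too — and is deliberately not subtracted.

**What the generator does not emulate:** realistic EMG spectra, habituation
across trials, artifact contamination beyond the window checks,
between-index correlations beyond those the construction induces, and any
within-patient correlation between demographics and indices.  Passing
round-trip tests therefore validates the extraction and asymmetry
arithmetic, not the behaviour of the pipeline on real recordings.

## The fixture cohort

`fixture_cohort()` is hand-placed, not sampled: exactly 12 PD and 1 CBS
above the blink-reflex cutoff, exactly 7 CBS and 2 PD above the MRI
cutoff, the two blink-reflex-negative PD patients also MRI-negative, the
one blink-reflex-positive CBS patient also MRI-positive, and the whole
cohort linearly separable (witness direction: AI of R2BRRC − 20·AI of
MRI).  It deterministically reproduces the published single-index
sensitivities/specificities, their exact confidence intervals, and the
perfect combined classification.  Its in-sample Youden cutoffs and
empirical AUCs are *not* published quantities — per-patient data were
never released — and the package does not claim to reproduce the published
empirical AUCs of 0.94 and 0.77; the binormal bridge from the published
group summaries (0.94 at ISI 100; 0.75 for MRI against the published 0.77)
is the reproducible counterpart.

## Problem sizes and numerics

Distributional-recovery tests and the acceptance script use 10,000
patients per group in summary mode; trace-mode round-trip tests use 40 per
group with the default 5 trials, and small noise-free batteries where
exactness is asserted.  Monte-Carlo margins are set at 3–4 standard errors
of the quantity under test.  Degenerate inputs fail fast with specific
errors: zero unconditioned amplitude (no measurable baseline R2), both
sides zero in the asymmetry index, single-class ROC input, invalid
configuration keys (rejected before any stage runs).  All randomness flows
from explicit integer seeds; the pipeline manifest records MD5 checksums
of every text artifact, and re-running a configuration reproduces them
byte for byte (the ROC figure PDF is excluded from checksumming because
the PDF format embeds a creation timestamp).

## Limitations

Evaluation is in-sample on n = 24, mirroring the original exploratory
design: no cross-validation, no optimism correction, and no confidence
interval for the AUC.  The sequential combination rule is provided for
transparency but cannot reproduce the published perfect combination (see
above).  Real-data ingestion covers the CSV + JSON-sidecar trace format;
EDF reading is not included.
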