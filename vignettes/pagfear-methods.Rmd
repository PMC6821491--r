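---
title: "Methods: screening, classifying and decoding cue-inhibited vlPAG units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, classifying and decoding cue-inhibited vlPAG units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pagfear)
```

## The task and the data model

The pipeline analyzes single-unit recordings made while an animal performs
Pavlovian fear discrimination over rewarded nose poking. A session presents
32 ten-second auditory cues — 6 danger (shock probability 1.00), 16
uncertainty of which 6 are shocked (probability 0.375), 10 safety
(probability 0.00) — in random order with a mean inter-trial interval of
3.5 min; foot shock arrives 2 s after cue offset on shocked trials. Three
plain tables describe a session: events (cue on/off, shocks, pokes), spikes
(unit, timestamp) and mean waveforms (unit, time, voltage).

Fear on each trial is the conditioned-suppression ratio
$(b - c)/(b + c)$, where $b$ and $c$ are the baseline and cue poke rates.
The ratio is undefined (0/0) when the animal pokes in neither window; such
trials are excluded from means and from fear-output regression rather than
imputed, and excluded counts are visible in the per-trial table.

## Normalization

Firing is binned at 250 ms from 20 s before cue onset to 20 s after offset
(200 half-open bins per trial, cue onset opening bin 81). Differential
firing subtracts each trial's 2-s pre-cue mean from that trial's bins; the
differentials of all bins of all trials are then jointly Z-transformed.
Pooling all 200 bins (not just pre-cue bins) keeps units with sparse
baseline activity normalizable; a unit whose differential firing has zero
pooled variance is flagged unnormalizable and dropped, with the drop
recorded. The pooled SD uses the population divisor $N$ by default
(`sd_type` switches to $N-1$); with 6,400 bin values per unit the two
differ by under 0.01%, but the choice is explicit because the normalized
values feed every later stage. Normalization is exactly idempotent:
re-normalizing a normalized matrix reproduces it, which the suite asserts.

## Screening and classification

Screening asks, per unit, whether raw firing in the first or last 5 s of
danger or uncertainty is below the 10-s pre-cue baseline, with paired
two-tailed t-tests across trials (pairing per trial, baseline against
window of the same trial; the pairing unit is a package choice since only
the test and windows are prescribed). The per-comparison threshold is fixed
at $p < 0.0125$, the printed value for this screen. Comparisons with
zero-variance differences have no t statistic and count as non-significant.
Units significant only to safety can be excluded before clustering
(`screen_safety`), mirroring the practice of dropping safety-responsive
units.

Inhibited units are clustered by k-means (k = 2, Euclidean, best of 100
seeded restarts) on their mean early- and late-danger Z. Features are not
re-standardized: both coordinates are already on the common Z scale, and
rescaling them would distort the early/late geometry that separates the
populations. The cluster with the higher late-danger centroid is labelled
Flip; ties cannot occur unless the centroids coincide, in which case the
input was degenerate and an error is raised. Waveform comparisons use
pooled-variance t-tests (df $n_1 + n_2 - 2$).

## Encoding regression and tuning

Normalized firing is averaged into 14 one-second intervals (2 pre-cue, 10
cue, 2 post-cue). For each interval, firing across the 32 trials is
regressed on a regressor; the reported beta is standardized (firing is
already Z-scored; the regressor is z-scored across trials), so for the
default `separate_simple` mode the beta equals the Pearson correlation and
fear-output and threat-probability betas are directly comparable. The two
regressors are themselves correlated, so a `joint` mode (both regressors in
one OLS per interval) is provided; with orthogonalized regressors the two
modes agree to numerical precision, and the suite asserts this. The default
is `separate_simple` — one regressor at a time — because the single-regressor
beta is the quantity the tuning sweep varies; this is a package choice, not
a claim about the original toolchain, which did not state its regression
layout or standardization.

The tuning curve refits the probability regression for nine uncertainty
assignments (0 to 1 in 0.125 steps; danger and safety fixed at 1 and 0).
Betas are averaged over the epoch's five cue intervals within unit, then
across units — averaging in that order matters when units differ in
variance. The extremum is the grid point of maximal $|\bar\beta|$, reported
as a peak if positive and a trough if negative. At $q = 1$ the regressor
degenerates to the danger-or-uncertainty indicator and at $q = 0$ to the
danger indicator, which the suite asserts on constructed regressors.

## Shared statistics

* **Studentized bootstrap CI** (default 95%, 1000 resamples, seeded): each
  resample mean is studentized by its own SE and the t-quantiles are
  inverted around the observed mean. The resample SE defaults to the
  plug-in estimate $s^*/\sqrt{n}$, which is the exact plug-in SE for a mean
  and makes the 1000-replicate coverage check fast; a nested-bootstrap SE
  (`se_method = "nested"`, 50 inner resamples) is available, and a test
  checks the two constructions agree. Constant input yields the degenerate
  interval $[c, c]$ with a warning.
* **Sign test**: zeros excluded, exact two-tailed Binomial(n, 1/2) on the
  positive count (equivalent to twice the smaller tail, capped at 1); the
  suite verifies this against direct binomial arithmetic for every
  $n \le 20$.
* **Repeated-measures two-factor ANOVA**: balanced subjects × A × B arrays,
  each effect tested against its subject-by-effect interaction, uncorrected
  df (no sphericity correction — a documented limitation), partial
  $\eta^2 = SS_e/(SS_e + SS_{err})$. The decomposition is computed directly
  from cell means, which makes null-calibration simulations cheap; the
  suite cross-checks F and p against `aov()` error strata and the sums of
  squares against explicit loops.
* **Pearson correlation** reported as $R^2$ with the two-tailed t-transform
  p-value.

## The synthetic-session generator

The generator exists so that every stage can be validated against planted
ground truth; its defaults are the task's study conditions plus explicit
assumptions where the task description is silent:

* **Schedule**: exact 6/6/10/10 design, uniformly permuted; ITIs are a 50-s
  floor plus an exponential with overall mean 210 s. Only the mean ITI is
  given by the task, so the memoryless shape is an assumption (the
  conditioning-default choice); the floor guarantees that neighbouring
  trials' 20-s alignment windows never overlap.
* **Poking**: Poisson at 0.6 pokes/s outside cues, multiplied by
  $1 - f_{\text{cue}}$ inside cues, $f$ = danger 0.92, uncertainty 0.71,
  safety 0.10. A suppression fraction $f$ yields an expected ratio
  $f/(2-f)$, so these place the mean ratios near 0.85/0.55/0.05 — the
  discriminative profile of well-trained animals. Session poke statistics
  are not stated in the task description, so the rate is an assumption
  labelled in the config.
* **Spiking**: inhomogeneous Poisson, baseline 10 Hz (typical of these
  units), multiplied by archetype-specific early/late gains during the two
  cue halves (flip: danger 0.2 then 2.0; sustain: danger 0.3 throughout;
  onset-excited and flat controls). No refractoriness is modelled — every
  downstream statistic is rate-based, so a renewal model would add
  parameters without adding test surface. The early/late split at the cue
  midpoint matches the analysis windows.
* **Waveforms**: a difference-of-Gaussians biphasic template with settable
  amplitudes and peak-to-trough time, so half-duration and amplitude-ratio
  ground truth is analytic; per-unit jitter makes population comparisons
  non-degenerate. The template has a single hyperpolarization lobe, so the
  "initial hyperpolarization" of the amplitude ratio is measured at the
  global post-peak minimum.
* **Seeding**: one master seed; the schedule, poke train and every unit
  draw from sub-seeds derived from it by a seeded draw without
  replacement, so sessions are bit-reproducible and units independent.

What the generator does *not* emulate: learning across sessions,
shock-evoked firing (the 500-ms shock window is excluded from analysis by
design), spike-sorting noise, bursting/refractory structure, and slow
drifts in excitability. Passing planted-recovery tests therefore shows the
chain is correct and well-calibrated for rate-coded responses of the
assumed shapes, not that it is robust to every pathology of real
recordings.

## Validation scales and numerical choices

The suite validates at these problem sizes (chosen to keep the full run in
a few minutes on one core while leaving Monte-Carlo error well below the
tested margins): planted Flip/Sustain recovery over 100 seeded sessions of
80 units; tuning-assignment recovery for planted $q^* \in \{0.125, 0.375,
0.750\}$ over 100 seeds of 200 units at noise SD 0.3; screening
false-positive calibration on 10,000 flat units against a 3-binomial-SE
band (pooled per-comparison rate — the four comparisons of a unit share a
baseline, so the pooled band at $n = 10{,}000$ is conservative); bootstrap
coverage over 1000 replicates of $n = 100$ normal samples; ANOVA type-I
calibration over 500 null simulations.

Degenerate inputs are handled explicitly rather than silently: zero-rate
suppression ratios are NaN; constant units are unnormalizable errors;
zero-variance t-test differences are non-significant with NA statistics;
identical clustering features, all-zero sign tests and constant bootstrap
input raise or warn as documented above. Bins and windows are half-open
`[t, t + w)` throughout, so a spike exactly at cue onset belongs to the
first cue bin.

## Known limitations

Uncorrected ANOVA df assume sphericity; the screen's alpha is fixed at the
printed 0.0125 even though a six-comparison Bonferroni correction would be
0.0083 (the screen makes four danger/uncertainty comparisons, plus two
safety comparisons used only for exclusion); post-hoc "observed power" is
deliberately not computed; and real-data headline counts (e.g. cluster
sizes) are properties of the original recordings, which this package treats
as out of scope — the synthetic-recovery tests are the corresponding
guarantees.
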