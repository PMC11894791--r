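---
title: "Models and methods behind erpmem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind erpmem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpmem)
```

erpmem bundles three statistical machines — a spatiotemporal cluster-mass
permutation test, signal-detection recognition indices with a
recollection/familiarity split, and random-intercept mixed models with
Satterthwaite degrees of freedom — together with a synthetic-data generator
shaped like the two taVNS/emotional-memory study designs it is meant to
exercise. This vignette explains the models, the defaults, and the choices
made where the design was genuinely open. Every number quoted here is
computed by the package's tests or its acceptance script; none is imported
from elsewhere.

## The synthetic designs

`build_design()` emits trial-level tables for two designs:

* **Study 1 shape** (default 30 subjects, within-subject cross-over): a
  pool of 240 images (120 neutral, 120 unpleasant) in four counterbalanced
  sets of 60; two encoding sessions of 60 scenes (one under taVNS, one
  under sham, order alternating across subjects); retrieval of all 120
  encoded images intermixed with 120 new ones. Confidence is an 11-point
  anchor scale 0–10.
* **Study 2 shape** (default 65 subjects, mixed): stimulation between
  subjects; one encoding session of 120 images presented in alternating
  on/off stimulation half-cycles of exactly 4 images; retrieval with 120
  old + 120 new items on a 6-point scale (anchors 1–3 = "new",
  4–6 = "old").

Encoding orders are pseudorandomized with no more than two same-category
scenes in a row. Rather than rejection-sampling whole permutations (whose
acceptance probability for 60 balanced trials is on the order of 10⁻⁶), the
generator draws categories sequentially with probability proportional to
the remaining counts, excluding a third repeat, and restarts on the rare
dead end. This guarantees the constraint by construction; the distribution
over admissible sequences is close to, but not exactly, uniform — a
difference none of the downstream statistics can see.

All stages derive their RNG streams from one root seed through fixed
offsets, so each stage is independently reproducible and whole runs are
bit-identical given (config, seed).

## The dual-process behavior generator

An old item is *recollected* with per-cell probability R, producing an
"old" response at the top confidence anchor. Otherwise its familiarity
strength is drawn from Normal(d_fam, 1) and binned through strictly
increasing criteria into a confidence anchor; new items draw from
Normal(0, 1) (false recollection is 0 by default and configurable). For the
6-point dialect, five criteria produce anchors 1–6 and anchors ≥ 4 mean
"old". For the 11-point dialect, ten criteria produce an oldness axis 0–10
with "old" iff anchor ≥ 6; the stored confidence equals the anchor for
"old" responses (recollection = 10) and 10 − anchor for "new" responses,
mimicking the two-question (old/new then confidence) format. New-response
confidences are never used by any downstream statistic.

Defaults, chosen once to look like week-delayed scene recognition and to
express the qualitative pattern the designs are built around: old/new
criterion 0.75 on the strength axis (false-alarm rate ≈ 0.23); d_fam = 1.1;
R = 0.33 with 0.40–0.42 in the unpleasant/taVNS cells, so that
recollection-based Pr clearly exceeds familiarity-based Pr and the
emotional-stimulation cells show a recollection advantage. An early default
(R ≈ 0.22) turned out to make the recollection and familiarity Pr almost
exactly equal — an accident of the criterion placement that contradicted
the pattern the generator is supposed to emulate — and was revised to the
present values.

The generator's rates have closed forms (mixtures of the recollection mass
at the top anchor and Gaussian bin masses), which the tests use for
3-standard-error parameter-recovery checks at ~10,000 trials.

## The ERP generator and its noise model

`gen_epochs()` produces per-subject, per-condition *average* ERPs directly:
injected patch amplitudes (plus per-subject patch deviations and a
per-subject spatially smooth offset) over correlated noise. The noise is
white Gaussian sensor noise mixed by a small number of diffusion passes
over the sensor adjacency graph (each pass averages a sensor with its
neighborhood mean) with AR(1) dependence along time; the combined operator
is row-rescaled so the marginal SD equals the configured value exactly,
which is what makes the tests' law-of-large-numbers checks sharp. Defaults:
SD 1 µV at the average level, 2 diffusion passes, AR coefficient 0.5,
subject offset SD 0.5 µV. The spatial smoothing is the minimal model that
makes spatial clustering non-trivial; nothing about real EEG volume
conduction is claimed.

A packaged Fibonacci-lattice layout on the upper hemisphere stands in for
a proprietary 129-channel geodesic montage, with the distance threshold
chosen to give a median of ~6 neighbors and conventional `posterior` /
`anterior` masks (y ≤ −0.15 / y ≥ 0.15). Every analysis takes the layout as
an argument, so a real montage supplied via `read_layout()` drops in.

What the generator does **not** emulate: raw continuous EEG, artifacts,
filtering, trial rejection, volume-conducted dipolar topographies, or
item-level variability in ERPs. Passing tests therefore demonstrate that
the *statistics* behave as specified on data with the declared covariance
structure — not that any particular neural claim holds on real recordings.

## The cluster-mass permutation test

The forming step computes, per sensor-time point, F = t² of the
per-subject effect contrast (one-sample for within-subject effects, df
(1, n−1); pooled two-sample across groups for mixed effects, df
(1, n₁+n₂−2)). Points with p below the forming alpha (default 0.05) that
persist for at least `min_run` = 5 consecutive samples (20 ms at 250 Hz)
survive; survivors are linked within a sensor across adjacent samples and
within a sample across neighboring sensors, and connected components become
clusters with mass Σ F. Two readings of the forming rule are possible —
temporal-only runs or full spatiotemporal clustering — and only the
combination (per-sensor duration prefilter, then spatiotemporal linking)
yields the multi-sensor single-window clusters such analyses report, so
that is what `form_clusters()` implements. The kernel (run filter +
union-find) is compiled C++; an igraph-based brute-force oracle checks it
on small grids in the tests.

The null resamples the *maximum* cluster mass per permutation — the
max-statistic construction that controls family-wise error — rather than
pooling all permuted clusters, which would not. Within-subject 2-level
effects are resampled by independent per-subject sign flips of the
contrast (exact exchangeability under the null); between-subject factors
by group-label permutation preserving group sizes; interactions in mixed
designs permute group labels while keeping the within-subject structure
intact. The critical mass is the 95th percentile (default type-7 quantile)
of the null sample, and clusters also receive the add-one permutation
p-value (1 + #{null ≥ M})/(1 + n_perm), so the smallest attainable p is
1/(n_perm + 1). Degenerate zero-variance points map to F = 0 (zero mean) or
a flagged large sentinel (nonzero mean) rather than being dropped.

Cluster windows are reported as half-open [first sample, last sample + 4 ms)
intervals; sample i covers [tᵢ, tᵢ + 4 ms) at 250 Hz, which keeps the
5-samples-equals-20-ms arithmetic exact.

Calibration contracts, both runnable in minutes and checked in the test
suite: (i) on 200 simulated null datasets (16 subjects, 32 sensors, 64
samples, 500 permutations) the fraction with any significant cluster stays
within one-sided binomial error of 0.05; (ii) an injected 2×2 interaction
patch at per-subject contrast-to-noise 1 (patch amplitude = 2 × noise SD,
since the double-difference contrast of unit-variance cells has SD 2) with
26 subjects is recovered with spatiotemporal Jaccard ≥ 0.5 in at least 80%
of replicates. ROI masks are applied *before* both the forming step and the
null (the alternative — masking only the empirical map — would mix
search spaces of different sizes).

## Recognition indices

Pr = hit − FA and d′ = z(hit) − z(FA). Rates of 0 and 1 are replaced by
1/(2N) and 1 − 1/(2N) (N the relevant trial count) before the quantile
transform, the standard correction, recorded in the output; e.g.
d′(1, 0) with 30 + 30 trials is 2·z(59/60) ≈ 4.256. The
recollection/familiarity split keeps denominators at all old (new) trials
and restricts only the numerators (top-anchor vs sub-top "old" responses),
which makes the split exactly additive — a count identity the tests assert.
Published splits that are *not* additive must use a different (or rounded)
denominator convention; the package declares its own rather than guessing.
Subjects with overall Pr ≤ 0 are excluded with a report
(`exclude_poor_performers()`), and numerator classes with fewer than 5
trials are flagged `unstable` but still computed.

## Random-intercept mixed models

`fit_lmm_ri()` fits the two-variance-component model by REML, profiling
λ = σ²_s/σ²_e on the log scale with closed-form GLS per evaluation
(per-subject rank-one updates, no general matrix inversion), tolerance
1e-10, with an explicit boundary comparison at λ = 0. The response is
centered internally when an intercept is present purely for numerical
stability (translation invariance of the variance components then holds to
optimizer precision). Factors are coded sum-to-zero so main effects remain
interpretable under interactions; p-values are two-sided from the t
distribution at the Satterthwaite df.

The Satterthwaite df use the delta method: df = 2f²/(∇f' V ∇f) where f is
the contrast variance as a function of (σ²_s, σ²_e), ∇f its analytic
gradient, and V the inverse expected REML information. On balanced designs
this reproduces the classical identities exactly — 30 subjects × 2×2 gives
87 for every within effect, 2×2×2 gives 203 — and on random balanced and
unbalanced datasets the tests require agreement with lmerTest to 1e-6 on
coefficients and 1e-3 on df. One subtlety the tests encode: when the
subject variance lands on the λ = 0 boundary, the estimates collapse to
ordinary least squares but the Satterthwaite df still partition by stratum
(within effects get N − n_subjects − (rank−1), the intercept n_subjects − 1),
which is also what lmerTest reports — not the pooled OLS residual df.

Bayes factors use the BIC approximation BF₁₀ = exp((BIC₀ − BIC₁)/2) on ML
refits, with the conventional anecdotal/moderate/strong/very strong/extreme
bands attached. This is a deliberate substitution for default-prior
Bayesian ANOVA: it is monotone in the evidence for these designs, but its
values are not comparable to JZS-prior Bayes factors and the package does
not present them as such.

## Pipeline, formats, determinism

`run_study()` chains simulate → exclude → indices → mixed models + Bayes
factors → windowed cluster tests → follow-ups. Analysis windows follow the
studies' practice — encoding 200–600 and 600–1200 ms over the posterior
ROI, retrieval 400–1000 ms over anterior + posterior — and are tested
independently with no cross-window correction; the report says so in its
provenance block. Retrieval follows the two-stage logic: the
category × stimulation interaction is tested among old-item ERPs, and
significant clusters are then compared against correctly-identified-new
baselines with paired t-tests (a full 2×2×2 with old/new is impossible
because new items cannot be split by encoding stimulation).

Tables travel as TSV, cluster results and reports as JSON, configurations
as YAML, and epoch arrays as RDS with a JSON metadata sidecar (subjects,
conditions, sensors, time axis, sample rate, baseline). `analyze_study()`
re-runs from saved intermediates without re-simulation, and report payloads
contain no timestamps, so identical (config, seed) runs write identical
bytes.

Problem sizes used by the shipped checks — 200 null datasets × 500
permutations for the error-rate calibration, 20 replicates for recovery,
~10,000 trials for behavioral parameter recovery, 1000 permutations in the
worked examples — were chosen as the smallest sizes at which the binomial
and Monte-Carlo error bars are decisively narrower than the contracted
margins.

## Known limitations

* The layout is synthetic; `posterior`/`anterior` are conventions, not a
  reconstruction of any published montage.
* The noise model is graph-diffused AR(1) Gaussian at the condition-average
  level; it calibrates cluster statistics but does not model single-trial
  counts, artifacts, or realistic scalp topographies.
* No TFCE, cluster-extent statistics, time–frequency analysis, source
  localization, random slopes, crossed item effects, or ROC-based
  dual-process estimation.
* The BIC Bayes factor is an approximation with a unit-information-prior
  flavor; use it for direction and order of magnitude, not as a drop-in
  for JZS values.
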