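# erpmem

Simulation and analysis toolkit for event-related-potential (ERP) studies of
emotional episodic memory under transcutaneous auricular vagus nerve
stimulation (taVNS) — and, more generally, for any 2×2(-ish) within/mixed
ERP design that needs spatiotemporal cluster statistics, signal-detection
memory indices, and random-intercept mixed models in one reproducible
pipeline.

The package is aimed at EEG/ERP researchers who want to

* **simulate** study-shaped data with known ground truth: multi-sensor ERP
  epochs (129-channel-style layouts, 250 Hz, −200…1200 ms) with effect
  patches injected over spatially and temporally correlated noise, plus
  trial-level old/new recognition behavior from a dual-process
  (recollection/familiarity) generative model;
* **test** condition effects with the two-step cluster-based permutation
  procedure, and follow up with repeated-measures ANOVAs and t-tests on
  cluster-averaged amplitudes;
* **quantify** recognition memory with Pr and d′ per stratum, split into
  recollection- and familiarity-based components by confidence, and model
  them with random-intercept linear mixed models (Satterthwaite degrees of
  freedom, BIC-approximate Bayes factors).

## The statistics at the core

**Cluster-based permutation test.** For every sensor *s* and sample *t* a
pointwise *F* statistic of the effect contrast is computed (for 2-level
factors, *F* = *t*²). Points with *p* < 0.05 sustained for at least 5
consecutive samples (20 ms at 250 Hz) survive; surviving points are linked
across adjacent samples within a sensor and across neighboring sensors
within a sample, and each connected component becomes a cluster with mass
*M* = Σ *F*. The null distribution of the **maximum** cluster mass is built
from 1000 permutations (per-subject sign flips of the within-subject
contrast; group-label permutation for between-subject factors); the
**critical cluster mass** is its 95th percentile, which controls the
family-wise error rate across the whole sensor × time grid. Each empirical
cluster also gets *p* = (1 + #{null ≥ *M*}) / (1 + n_perm).

**Recognition indices.** Pr = p(hit) − p(false alarm) and
d′ = z(hit) − z(false alarm), with extreme rates replaced by 1/(2N) before
the quantile transform. Recollection-based indices restrict the numerators
to top-confidence "old" responses, familiarity-based indices to sub-top
"old" responses, while denominators stay at all old/new trials — so
recollection + familiarity = overall, exactly.

**Mixed models.** `fit_lmm_ri()` estimates
y = Xβ + b_subject + ε, b ~ N(0, σ²_s), ε ~ N(0, σ²_e) by REML (profiled
variance ratio, closed-form GLS) with sum-to-zero factor coding, and
attaches Satterthwaite denominator df to every fixed-effect *t* via the
delta method over the two variance components. On balanced data the df
reproduce the classical identities (e.g. 30 subjects × 2×2 → df = 87 for
within effects; 2×2×2 → df = 203). `bf10_bic()` compares nested models via
BF₁₀ = exp((BIC₀ − BIC₁)/2).

## Worked example

Simulate 26 subjects of a 2 (category) × 2 (stimulation) within design with
a known interaction patch at 400–700 ms over posterior sensors, then test
the interaction:

```r
library(erpmem)

lay <- sensor_layout(32)
cfg <- erp_config(
  n_sensors = 32, window = c(-200, 1200),
  noise = list(sd = 1, spatial_smooth = 2, ar = 0.5, subject_sd = 0.5),
  effects = list(effect_patch(window = c(400, 700),
                              amplitude = c(unpleasant.taVNS = 2),
                              center = lay$rois$posterior[1], radius = 2,
                              subject_sd = 0.3)))
d   <- build_design(1, n_subjects = 26, seed = 7)
ep  <- baseline_correct(gen_epochs(cfg, d, lay, seed = 7))
eff <- effect_spec("category x stimulation", "interaction_within",
                   list(a = c("unpleasant.taVNS", "unpleasant.sham"),
                        b = c("neutral.taVNS",   "neutral.sham")))
res <- cluster_test(subset_epochs(ep, window = c(200, 1200)), eff, lay,
                    n_perm = 1000, seed = 7)
res
#> <perm_result> effect 'category x stimulation': 1 cluster(s), 1 significant
#>   (critical mass 134.12, 1000 permutations)
#>   cluster   mass n_points t_start t_end duration_ms  p_value significant
#> 1       1 19396.      749     400   700         300 0.000999 TRUE
```

The test recovers the injected patch exactly (400–700 ms; p = 1/1001, the
smallest value 1000 permutations allow; its mass 19396 dwarfs the critical
mass 134 drawn from the max-mass null). `cluster_mean_amplitude()` then
feeds the follow-up ANOVA, and `autoplot(res)` shows the null histogram
with the critical mass and the observed clusters.

On the behavioral side:

```r
b   <- gen_recognition(d1 <- build_design(1, n_subjects = 30, seed = 7),
                       behavior_config("eleven_point"), seed = 7)
idx <- memory_indices(b, c("subject", "category", "stimulation"))
fit <- fit_lmm_ri(subset(idx, memory_class == "overall"),
                  pr ~ category * stimulation)
tidy(fit)
#>   term                   estimate std.error statistic    df  p.value
#> 1 (Intercept)             0.47      0.00954    49.2    29   1.66e-29
#> 2 category1              -0.00278   0.00922    -0.301  87.0 7.64e- 1
#> 3 stimulation1            0.00694   0.00922     0.753  87.0 4.54e- 1
#> 4 category1:stimulation1 -0.00250   0.00922    -0.271  87.0 7.87e- 1
```

Note the Satterthwaite df of 87 = 120 − 30 − 3 for every within-subject
effect — the balanced-design identity — while the intercept gets the
between-subject df of 29.

`run_study(run_config(study, seed))` chains all of this (simulate →
exclude → indices → mixed models + Bayes factors → windowed cluster tests →
follow-ups) into a single deterministic report; `inst/cli/erpmem` exposes
`simulate` / `analyze` / `report` subcommands for shell use.

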