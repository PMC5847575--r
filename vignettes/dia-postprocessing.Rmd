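---
title: "Post-processing large DIA cohorts: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-processing large DIA cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`diaq` post-processes precursor-level DIA (SWATH) quantification reports from
large, batched cohorts. This vignette is the package's account of the science:
the models behind each stage, the parameters that matter, what the synthetic
cohort generator does and does not emulate, and the numerical decisions taken
where the design was genuinely open.

## The problem

A cohort of hundreds of injections is acquired over weeks, in batches. Three
technical nuisances dominate the extracted signal: run-to-run injection
differences (a per-run global scale), batch effects tied to acquisition
periods (feature-specific shifts and variance changes shared within a batch),
and chromatographic drift (retention times sliding between runs). A pooled QC
sample — a mixture of all study samples — injected every 10–12 runs provides a
biology-free readout of all three. The pipeline's fixed stage order is:

1. Qvalue filtering (precursor completeness policy),
2. pivot to a precursors × runs matrix; log2 transform,
3. robust-sum injection normalization (linear scale),
4. retention-time calibration and stability metrics (side channel),
5. batch correction (empirical Bayes, or surrogate variables),
6. correlation-based peptide selection and geometric protein rollup,
7. CV and batch-clustering diagnostics.

All internal statistics operate on log2 intensities; CVs are reported on the
linear scale (SD/mean, %), the standard precision currency of proteomics QC.
Zeros in a DIA report denote non-detection and are treated as missing on the
log transform, never as −∞.

## Retention-time calibration

Spiked iRT standard peptides have fixed, dimensionless reference retention
values. Per run, observed apex RT (seconds) is regressed on reference iRT by
ordinary least squares; `to_irt()` inverts the map. OLS is the default because
the calibration is defined as linear; a Theil–Sen median-of-slopes estimator
(`method = "robust"`) is available for runs with outlier standards. Runs with
fewer than two detected standards are flagged unfit rather than dropped, so
downstream code can decide. Stability metrics: per-standard SD (sample SD,
n−1, appropriate for the small number of standards) and CV of raw apex RTs
across runs, and per-run R² of observed versus predicted RT. The metrics are
computed over all detected standards, with the count reported, since which
subset of a standard kit a lab monitors varies. Note that CV (%) of retention
time depends on the mean RT: very early-eluting standards can show CVs of
several percent at the same absolute jitter that gives < 1% for mid-gradient
peptides.

## Qvalue filter policies

Each precursor is kept or dropped as a whole; kept precursors retain their
intensities in all runs (precursor-level filtering, so one poor extraction
does not punch holes in the matrix). With "passing" meaning a measured
qvalue ≤ cutoff (default 0.01):

* *sparse* keeps a precursor passing in ≥ 1 run,
* *complete* requires measurement and passing in **every** run,
* *percentile(p)* requires a passing fraction ≥ p,
* *median* requires a passing fraction ≥ 0.5.

Two readings in the literature deserve a note. First, "sparse filtering,
retaining every precursor with at least one value **above** the threshold" is
read here as a slip for *below*: keeping only precursors with at least one
*failing* value would discard exactly the cleanest identifications. Second,
"median Qvalue ≤ cutoff" is implemented as the lower-median / "at least half
of runs pass" rule. For odd run counts the two readings coincide; for even
counts the interpolated median of, say, (0.001, 0.001, 0.5, 0.5) is 0.25 and
would fail, breaking the natural policy ordering. The ≥ 50% rule makes
*median* exactly *percentile(0.5)* and guarantees the nesting
complete ⊆ median ⊆ percentile(p ≤ 0.5) ⊆ sparse, which the test suite checks
on randomized cohorts. The literal median qvalue is still reported in the
filter audit for inspection.

A missing qvalue counts as failing. The pass-fraction denominator is the
cohort run set (an optional `runs` argument covers runs that contributed no
rows at all).

## Robust-sum normalization

Injection differences are a per-run global scale. The corrector equalizes a
robust total: precursors are ranked by the cross-run median of their
*run-median-normalized* intensities; the top and bottom `pool_fraction`
(default 0.10) are excluded; the pool is further restricted to precursors
measured in every run so each run's robust sum `S_r` adds identical members;
each run is rescaled by `f_r = median(S)/S_r`.

Two numerical choices make the operation well-behaved:

* ranking on run-median-normalized intensities makes the pool invariant under
  per-run rescaling, which in turn makes normalization **idempotent**;
* the target is the **lower median** — the robust sum of an actual run — so
  rescaling any other run leaves every normalized value unchanged (with an
  interpolated median, scaling one run would shift the global target for even
  run counts). Ties at the pool boundary break lexicographically by precursor
  id, for determinism.

An important identifiability consequence: equalizing run totals absorbs each
batch's *mean* (intensity-weighted) additive batch effect into the run
factors. What remains for the batch corrector is the feature-specific part —
which is also the only part that distorts relative quantification. Parameter
recovery on synthetic data is therefore assessed on per-batch-centered
effects.

## Empirical-Bayes batch correction

Per feature g in batch i, run j, the log2 signal is modeled as

y_ijg = α_g + X_j β_g + γ_ig + δ_ig ε_ijg,  ε ~ N(0, σ²_g)

with additive (γ) and multiplicative (δ) batch effects. The fit is feature-wise:

1. least squares of y on batch indicators plus covariates, with the
   constraint Σᵢ nᵢ γ̂_ig = 0 (the batch-size-weighted intercept); σ̂²_g is the
   mean squared residual;
2. standardization z = (y − α̂_g − Xβ̂_g)/σ̂_g (batch structure retained);
3. per-batch raw estimates: γ̂_ig = batch mean of z, δ̂²_ig = batch variance;
4. hyperpriors per batch by method of moments across features — a normal
   prior for γ (mean γ̄ᵢ, variance τ̄²ᵢ) and an inverse-gamma prior for δ²
   with λ̄ᵢ = (m² + 2s²)/s², θ̄ᵢ = (m³ + m·s²)/s² from the mean m and variance
   s² of the δ̂²_ig;
5. the posterior fixed point
   γ\* = (n τ̄² γ̂ + δ²\* γ̄)/(n τ̄² + δ²\*),
   δ²\* = (θ̄ + ½Σⱼ(z − γ\*)²)/(n/2 + λ̄ − 1),
   iterated until max |Δγ\*| < 1e-4 (at most 100 iterations; non-convergence
   is an error, not a warning).

Correction restores y\* = (σ̂_g/δ\*)(z − γ\*) + α̂_g + Xβ̂_g, so covariate
contrasts (genotype differences) are explicitly re-added. QC anchoring is
realized by making the sample type one level of the condition covariate
alongside the genotypes: QC runs then inform the batch estimates in every
batch without being modeled as a biological group. With `shrink = FALSE` the
raw per-batch estimates are used; the test suite proves this path equal to a
brute-force "standardize within batch, restore pooled location/scale" oracle,
and the shrunk path equal (to ~1e-14) to the reference Bioconductor
implementation on complete data.

Edge cases: features for which any batch has fewer than two measured runs are
passed through uncorrected and recorded (δ̂² undefined); zero-residual-variance
features likewise; a single batch is the identity correction by definition —
there is no batch structure to remove, and forcing the general formulas
through one batch would merely rescale by √((n−1)/n) due to the n vs n−1
variance denominators. Rank-deficient designs (a covariate level confined to
one batch) abort with the confounded columns named. Missing cells are never
imputed and never created.

## Supervised surrogate variables

The alternative corrector makes no use of experimental factors. Features are
ranked by variance across runs (variance on the log2 scale; CV ranking is a
config alternative the package deliberately does not default to, since on log
data variance is the natural spread measure); the least-variable 50% form the
control set, on the assumption that biology is flat there and what structure
remains is technical. The row-centered control submatrix is decomposed by
SVD; the top right singular vectors (runs × k, orthonormal) are the surrogate
vectors, regressed out of **all** features (controls included — regressing
only non-controls would leave the controls inconsistent) with the intercept
retained. `k = "auto"` keeps component j while its singular value exceeds the
95th percentile of the j-th singular values of 19 row-permuted controls
(seeded). The default is k = 1, matching the common case of one dominant
acquisition-date axis. The two correction modes are mutually exclusive in one
pipeline run.

## Peptide selection and rollup

Peptides of one protein should co-vary; those that do not (variable
post-translational modification, interference) are excluded *by correlation,
not abundance*. Per protein: each member's score is its mean pairwise Pearson
correlation (on log2, over runs where both members are measured; pairs
sharing fewer than `min_overlap = 6` runs score missing, and a member with no
scorable pair sorts lowest). Greedy backward elimination removes the worst
member and recomputes while the worst score < `rho_min` and more than two
members remain — one-shot thresholding would be cheaper but mean correlations
change after an outlier leaves. Ties break on (score, precursor id). Proteins
with ≤ 2 members keep all members, flagged `unselected`; selection never
drops a protein. `rho_min = 0.5` is exposed in config and the full selection
trace is persisted, so any threshold can be audited.

The protein value per run is the geometric mean of the selected members
present (arithmetic mean on log2), computed when at least
`min_present_fraction = 0.5` of them are measured. The atomic unit is the
precursor throughout; charge states of one peptide are distinct features (an
optional charge-collapse pre-step can be applied upstream, but the default
keeps the report's native unit).

## QC metrics and diagnostics

CVs are computed per feature per group on linear intensities; groups with
fewer than two measured values yield NA, never 0. Group families: QC runs
within one batch (intra-batch), all QC runs (cross-batch), and study
replicates of one strain across batches ("total" variability, which includes
biology). The variability-reduction summary is
100·(median_before − median_after)/median_before on the total CV; a negative
value (correction made things worse) is returned, not raised. Batch
clustering is quantified by feature-wise one-way batch R² and by the mean
silhouette width of batch labels in the first two principal components of the
complete-case, feature-centered matrix — a deliberately minimal diagnostic,
not an inference tool.

## The synthetic cohort generator

`truth_params()` encodes the emulated study: 38 strains × 8 replicates in 3
batches (~304 study runs), a QC injection opening and closing each batch and
after every 10–12 study runs (~33 QCs, ~337 runs total — published accounts
of such cohorts give strain, replicate and total counts that are not exactly
mutually consistent; the generator fixes 38 strains and sets replicates so
the cohort lands at the reported ~330-run scale). The log2 signal is

y = base_g + effect_{p(g),s} + a_{i,g} + d_{i,g}·ε + inj_j,

with protein-level strain effects (SD 0.5 log2) shared by a protein's
peptides — what makes correlation-based selection meaningful; additive batch
offsets a ~ N(0, 0.18²) and multiplicative factors d² from an inverse-gamma
with mean 1 (shape 50) — exactly the prior family the corrector assumes, so
parameter recovery is a fair test; technical noise with SD implied by a 12%
within-batch CV; and a per-run injection scale (SD 0.15 log2) for the
normalizer to remove. Together these give a cross-batch QC CV of ~17%,
matching the intra-12% / cross-17% pattern such cohorts report. QC runs carry
the pooled mean of all strain profiles. Retention times come from per-feature
reference iRT values through a per-run linear map (slope SD 0.002, intercept
SD 5 s) plus apex jitter of SD 17.7 s — jitter dominating, so the planted
value is recoverable from the per-standard SD. Dropout is logistic in log2
abundance (slope 0.8, midpoint 10.5 against a base abundance of N(14, 2)),
and 1% of cells are false identifications with qvalues above 0.01. Every run
contains the 11 iRT standards, exempt from batch effects and dropout (they
are spiked post-digestion).

What the generator does **not** emulate: peak shapes and interference (the
pipeline starts at extracted quantities), correlated missingness between
co-eluting peptides, nonlinear RT distortions, within-batch drift, shared
peptides between proteins, and heavy-tailed intensity errors. Passing tests
therefore demonstrate correctness of the estimators under the stated model
and realistic magnitudes — not robustness to every pathology of real
chromatography. The abundance-dependent dropout model in particular is a
stand-in; its parameters are configuration, not claims.

Determinism: a dataset is a pure function of `truth_params()` including its
seed; the only stochastic pipeline component (the surrogate-count permutation
null) is seeded from the pipeline config.

## Problem sizes

The shipped tests exercise the full default cohort (~1,380 precursors × 337
runs) once for the cohort-scale recovery checks — about half a minute of
compute — and small matrices (≤ 500 features, ≤ 40 runs) everywhere else;
the acceptance script re-runs the cohort end to end in well under a minute.
These sizes were chosen so the whole validation cycle stays interactive while
keeping every per-batch group large enough for stable CV and shrinkage
estimates.

## Known limitations

* No nonlinear RT alignment or RT prediction from sequence.
* No protein-level FDR estimation; filtering operates on precursor Qvalues.
* No non-parametric or reference-batch variant of the EB corrector, and no
  continuous (time-trend) batch model beyond what a surrogate vector captures.
* No peptide-to-protein inference: the precursor-to-protein map is taken as
  given by the spectral library.
* Isolation-window tiling is fixed-width; precursor-density-optimized
  (variable-width) schemes are out of scope.
* Printed cycle times of published methods mix dwell, survey and overhead in
  instrument-specific ways; `t_survey` is a free parameter (default 0.1 s)
  and no single value reproduces all printed cycle times, so cycle time is a
  derived convenience, not a calibrated quantity.
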