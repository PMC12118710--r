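---
title: "Models and methods behind rhythmdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rhythmdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmdiff)
```

# The problem

Around-the-clock omics studies sample two groups of animals (for example a
control and a receptor-knockout genotype) every 4 hours across a 24-hour
light:dark cycle, with a few independent replicates per time point, and ask
two questions per molecular feature: *is it rhythmic?* and *do its rhythm
parameters differ between the groups?* rhythmdiff implements this analysis
for feature-by-sample matrices — RNA-seq-like counts or continuous,
lipidomics-like abundances — together with the downstream phase statistics,
enrichment tests and a simplified differential-expression layer, and ships
a synthetic-data generator with known ground truth so the whole chain is
testable without any external dataset.

# The cosinor model

All rhythm inference is anchored on fixed-period (τ = 24 h) cosinor
regression,

$$ y(t) = M + A\cos\!\left(\frac{2\pi (t - \phi)}{\tau}\right) + \varepsilon, $$

fitted in its linear parameterisation
$y = M + \beta_s \sin(2\pi t/\tau) + \beta_c \cos(2\pi t/\tau)$, from which
$A = \sqrt{\beta_s^2 + \beta_c^2}$ and
$\phi = (\tau/2\pi)\,\mathrm{atan2}(\beta_s, \beta_c) \bmod \tau$.
*M* is the mesor (baseline), *A* the amplitude (half the peak-to-trough
span) and φ the acrophase (clock time of the fitted peak). Replicates at a
time point enter as independent observations; no averaging is done, which
matches how regression detectors are normally applied to this design.
Rhythmicity is the F-test of the two harmonic terms against the
intercept-only model. With Gaussian noise this test is exact, and on
log-transformed negative-binomial counts at realistic depths it is very
close to calibrated (the package's tests verify uniformity of the null
p-values by a Kolmogorov–Smirnov check at n = 10,000 features).

# Three detectors and a consensus rule

Published pipelines combine several rhythm detectors and call a feature
rhythmic when *at least one* method passes p < 0.01. rhythmdiff represents
the common detector families with three tests:

* **cosinor F-test** — the parametric harmonic-regression family;
* **JTK-style test** (`jtk_test()`) — nonparametric: Kendall's τ between
  the series and cosine templates peaking at each sampling lag; one-sided
  tail of the best lag, Bonferroni-corrected for the number of lags. The
  τ null tail is computed exactly (inversion-count enumeration) for
  untied series with n ≤ 10 and by the tie-corrected normal approximation
  otherwise;
* **Lomb–Scargle test** (`lomb_scargle_test()`) — the periodogram family:
  normalized spectral power at 1/24 h⁻¹ only (the period is fixed a
  priori, so no multiple-frequency correction applies).

For the Lomb–Scargle null we use the exact finite-sample tail for
sample-variance-normalized power under Gaussian noise,
$P(Z > z) = (1 - 2z/(n-1))^{(n-3)/2}$, which converges to the familiar
$e^{-z}$ for large n. At this design's n = 18 per group the exponential
tail is visibly anticonservative, and an anticonservative member would
break the union bound on the consensus false-call rate (the "any of k"
rule is bounded between α and kα); the exact form keeps every member
calibrated.

`consensus_rhythmicity()` implements `any` (default, the published rule),
`majority` and `all`. The detector set is an argument, so lipidomics runs
— conventionally analysed with one detector fewer — just pass a shorter
`methods` vector. No multiple-testing correction is applied to
rhythmicity p-values by default: the convention this follows uses a
stricter raw threshold (p < 0.01) instead, accepting inflated
false-positive control in exchange for sensitivity; a BH option is exposed
in the differential layer.

# Differential rhythmicity

`fit_differential_cosinor()` fits the two groups jointly by nonlinear
least squares (Levenberg–Marquardt, `minpack.lm`):

$$ y = (M + \Delta M\,G) + (A + \Delta A\,G)\,
   \cos\!\left(\frac{2\pi\,(t - (\phi + \Delta\phi\,G))}{\tau}\right)
   + \varepsilon, \qquad G \in \{0, 1\}, $$

initialised from the per-group linear fits, with Wald t-tests on ΔM, ΔA
and Δφ from the asymptotic covariance of the converged fit. A single fit
yields all three contrasts, which is why Wald rather than three
likelihood-ratio fits is used. Because the unconstrained model is an exact
reparameterisation of two independent per-group cosinor fits, the package
tests it against a separate-fits + delta-method oracle. Numerical notes:

* a start exactly at the per-group optimum can present a numerically
  singular Jacobian to the Levenberg–Marquardt QR when the two groups are
  identical; the fitter therefore falls back to slightly jittered and
  phase-rotated starts (up to `max_restarts`) before declaring
  non-convergence, and a non-converged feature is reported with per-group
  linear estimates and no p-values rather than aborting the run;
* the amplitude sign/phase gauge is normalised after convergence
  (A ≥ 0, φ ∈ [0, 24));
* Δφ is wrapped to (−12, 12] with **positive = group 2 peaks later**
  (a delay), and p for Δφ is suppressed when either amplitude is ≈ 0,
  where phase is unidentifiable;
* when `fix_dphi = TRUE` the shared-phase model couples the groups; its
  ΔM and ΔA coincide with the per-group linear differences when the two
  groups' phases genuinely agree (and ΔM does so on any balanced
  full-cycle grid).

`compare_rhythms()` applies the published gating: mesor and amplitude
contrasts are reported for features consensus-rhythmic in **at least one**
group ("a sine curve is fitted irrespective of thresholds"), the phase
contrast only for features rhythmic in **both** ("robustly rhythmic").
Contrasts with raw p below α = 0.05 become class labels (`mesor_up`,
`mesor_down`, `amp_up`, `amp_down`, `phase_delay`, `phase_advance`);
`summarize_drg()` tallies the UpSet-style class combinations. By default
no across-feature correction is applied, mirroring the practice this
implements; `adjust = "BH"` switches class assignment to FDR-adjusted
p-values. `mean_phase_shift()` averages the wrapped Δφ of robustly
rhythmic features and tests it against zero with a one-sample t-test
(Wilcoxon optional) — a linear test is appropriate because the shifts of
interest are small relative to the 24-h cycle; a circular test would be
needed for shifts approaching half a cycle.

# Phase statistics and enrichment

Acrophases are circular quantities; everything downstream respects that:

* `phase_histogram()` bins [0, 24) into widths that divide 24;
* `circular_median_hours()` is the member phase minimising summed
  shortest-arc deviations, ties broken toward the smaller hour —
  {23, 0, 1} has median 0, not 8;
* `circular_mean_hours()` is the direction of the resultant vector —
  23 h and 1 h average to 0 h. Category-level summaries use the circular
  mean deliberately (a naive arithmetic average is wrong whenever a
  category straddles midnight);
* phase set enrichment (`psea_kuiper()`) tests each gene set's acrophases
  against the background of all rhythmic features with the two-sample
  Kuiper test — the rotation-invariant circular analogue of the
  Kolmogorov–Smirnov test, V = D⁺ + D⁻ with Stephens'
  effective-sample-size asymptotic tail. Set members are removed from the
  background sample so the two samples are disjoint (overlapping samples
  would be dependent and the test would not calibrate). Phases are
  rounded half-up to whole hours before testing by default, matching the
  convention of feeding integer peak times into this analysis; rounding
  can be disabled, and with 4-hourly sampling it has little effect.
  Sets with fewer than `min_genes = 10` members are skipped with a
  reason, not dropped silently. The per-set summary phase is the circular
  median of member acrophases; `merge_categories()` then maps sets into
  curated broader categories (the curation is an input table, not an
  algorithm) and averages on the circle;
* over-representation (`ora_fisher()`) is the one-sided hypergeometric
  upper tail against an explicit background universe, reported for sets
  overlapping the hits in at least `min_genes = 3` features, with a BH
  column. No enrichment-graph pruning or semantic-similarity reduction is
  attempted.

# Differential expression (simplified)

`nb_global_test()` (all sampling times pooled) and
`nb_time_adjusted_test()` (categorical time + group vs time-only,
likelihood-ratio χ²₁) use negative-binomial GLMs with fixed per-feature
dispersions: method-of-moments estimates on size-factor-normalised counts,
a fitted mean–dispersion trend α(μ) = a₀ + a₁/μ, and log-space shrinkage
toward the trend. The residual cells differ by design: the time-pooled
test pools variance within groups (time variation is part of what its
model leaves unexplained), whereas the LRT pools within group × time
cells. Size factors are median-of-ratios. This is deliberately *not* a
re-implementation of the reference NB machinery — no Cox–Reid adjusted
profile likelihood, no fold-change shrinkage, no independent filtering —
so discovery counts on real data will not match that machinery's output;
the layer exists because the surrounding rhythm framework needs a sound,
calibrated expression test, and its calibration and power are verified by
simulation in the test suite. Direction calls use FDR < 0.05 and the sign
of the fold change only (no fold-change threshold).
`responsive_insensitive_sets()` provides the three-set algebra used to
isolate stimulus-responsive, receptor-insensitive features from published
DEG lists.

One compositional caveat demonstrated in the package's own tests: a
mesor shift applied to a large, one-sided fraction of features biases
median-of-ratios size factors (a property of all global-scaling
normalisations, not of this implementation). The generator's
`fraction_affected` and discrete-mixture effect specs exist so simulations
can mirror the realistic situation of a minority of affected features with
balanced directions.

# The synthetic-data generator

`generate_counts()` / `generate_lipidome()` emulate the standard design:
two groups × six 4-hourly time points × three replicates (both ZT0- and
ZT2-anchored grids are offered since either anchor occurs in practice).
Rhythmic signal is defined on the **log scale** —
mean(t) = exp(m + a·cos(2π(t − φ)/24)) — so cosinor fits to
log-transformed data are well specified. Count noise is negative binomial
(default dispersion 0.05, typical of gene-wise dispersions in inbred-mouse
liver RNA-seq); lipid noise is multiplicative log-normal (default σ = 0.2).
Default baselines (mesor ~ N(log 500, 1) for counts) give realistic
coverage; default amplitudes (uniform 0.3–1.5 on the log scale, i.e.
~1.3–4.5-fold peak-to-mesor) span weak to strong liver rhythms. The
default lipidome size, 285 species, matches a typical untargeted liver
run. Non-rhythmic features get amplitude exactly 0 — a clean null for
type-I-error calibration — and group-2 deltas follow the conventions:
Δmesor applies to every affected feature, Δamplitude and Δφ only to
rhythmic ones, with acrophase₂ = (acrophase₁ + Δφ) mod 24 and positive Δφ
meaning a delayed peak. One master seed spawns per-feature substreams, so
outputs are bit-reproducible. The generator does **not** simulate
read-level data, batch effects, sample swaps or missing-at-random lipid
dropout; passing tests demonstrate correctness of the estimators under
the stated noise models, not robustness to artefacts real datasets may
carry.

# Pipeline and problem sizes

`run_pipeline()` chains simulate/load → low-count filter (total across all
samples ≥ 100) → median-of-ratios + log2 transform (an approximate
variance-stabilising transform; the fitted dispersion trend of a full VST
is out of scope and the rhythm model only needs approximate
stabilisation) → detection (α = 0.01, rule `any`) → differential
comparison (α = 0.05) → phase statistics → optional PSEA/ORA → the two
expression tests, writing one TSV per stage plus a manifest with row
counts, the seed and a hash of the effective configuration; reruns with
the same configuration are byte-identical. The validation suite exercises
the chain at sizes chosen to make Monte-Carlo error small while keeping a
laptop-scale run: 10,000 features for null calibration, 500 for
differential-recovery and the end-to-end determinism check, 1,000 repeats
for the PSEA calibration, 100 series against the brute-force cosinor
oracle.

# Known limitations

* Period is fixed at 24 h; no ultradian or multi-harmonic fits, no period
  estimation.
* Raw-p thresholds for rhythmicity and contrasts follow the published
  convention and inflate false positives across thousands of features;
  the BH options are there for stricter analyses.
* Wald p-values from the nonlinear fit are asymptotic; at n = 18 per
  group they are close to calibrated (verified by simulation) but can
  misbehave for near-zero amplitudes, where the phase contrast is
  suppressed.
* The expression layer is a simplified NB GLM, not a drop-in replacement
  for the reference implementations.
* The lipid-name grammar covers the shorthand `CLASS C:D` notation with
  `_`/`/` chain lists, `O-`/`P-` prefixes and opaque `;` modifiers; full
  systematic sterol nomenclature and oxidised-lipid grammars are out of
  scope.
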