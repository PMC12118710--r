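# rhythmdiff

Differential analysis of diurnal rhythms in omics time courses.

## The problem

Around-the-clock experiments profile two groups — typically a control and a
perturbed genotype — by sampling tissue every 4 hours across a 24-hour
light:dark cycle with a few independent replicates per time point, using
RNA-seq, proteomics or lipidomics. Two questions are asked of every
molecular feature:

1. **Is it rhythmic?** Detected here by three complementary tests at a
   fixed 24-h period — cosinor harmonic regression (F-test), a JTK-style
   Kendall-tau template test, and a Lomb–Scargle periodogram test — with a
   feature called rhythmic when *at least one* method passes p < 0.01
   (the consensus rule is configurable).
2. **Do its rhythm parameters differ between groups?** Answered by a joint
   two-group cosinor fit,

   y = (M + ΔM·G) + (A + ΔA·G) · cos(2π (t − (φ + Δφ·G)) / τ),  G ∈ {0, 1},

   where M is the mesor (baseline), A the amplitude (half the
   peak-to-trough span) and φ the acrophase (clock time of the peak), with
   Wald tests on the three contrasts. Mesor and amplitude are compared for
   features rhythmic in at least one group; the phase contrast is reserved
   for features rhythmic in both. Significant contrasts become
   differential-rhythm classes (`mesor_up`, `amp_down`, `phase_delay`, …).

Around that core the package provides circular phase statistics
(wrap-aware means, medians, histograms, the mean phase shift with a test
against zero), Kuiper-test phase set enrichment with process-level phase
summarisation, hypergeometric over-representation analysis, a simplified
negative-binomial differential-expression layer (time-pooled Wald and
time-adjusted likelihood-ratio tests), a parser for shorthand lipid
nomenclature (`"TG 58:9"`, `"PC 18:1_20:3"`, `"Cer 18:1;2O/23:0"`), and a
synthetic two-group generator with known ground truth that makes the whole
chain testable end to end.

## Worked example

Simulate a study at the standard design (2 groups × 6 time points × 3
replicates), in which half the genes are rhythmic, rhythmic genes peak
0.4 h later in the knockout, and 30 % of genes carry a balanced ±0.4
log-mesor shift; then run detection and comparison:

```r
library(rhythmdiff)

cfg <- sim_config(
  n_features = 500, fraction_rhythmic = 0.5,
  delta_mesor = list(values = c(-0.4, 0, 0.4), prob = c(0.15, 0.7, 0.15)),
  delta_phase = 0.4, seed = 10)
sim  <- generate_counts(cfg)

xt    <- normalize_log(filter_low_counts(sim$matrix))
calls <- detect_rhythms(xt, alpha = 0.01, rule = "any")
table(calls$group, calls$consensus)
#>      FALSE TRUE
#>   KO   256  244
#>   WT   254  246

drg <- compare_rhythms(xt, calls, alpha = 0.05)
head(summarize_drg(drg), 4)
#>              combination  n
#> 1             mesor_down 35
#> 2               mesor_up 25
#> 3            phase_delay 18
#> 4 mesor_down+phase_delay  8

unlist(mean_phase_shift(drg))
#>         mean            n            p
#> 3.671111e-01 2.380000e+02 7.975904e-22
```

About 246 of 500 genes are called rhythmic in each group, matching the
simulated 50 % rhythmic fraction at the 1 % threshold; the mesor classes
split roughly evenly between up and down as simulated; and the mean
acrophase shift across the 238 robustly rhythmic genes is +0.37 h
(truth: +0.4 h, positive = knockout delayed), clearly distinguished from
zero. Single features work the same way through the model interface:

```r
f <- fit_cosinor(xt$values["gene_00004", xt$meta$group == "WT"],
                 xt$meta$time[xt$meta$group == "WT"])
f
#> cosinor fit (period 24 h, n = 18)
#>   mesor 8.118  amplitude 0.1717  acrophase 12.07 h
#>   rhythmicity p = 0.241 (F-test, df 2/15), R^2 = 0.173
```

`run_pipeline(pipeline_config(...), out_dir)` chains the full analysis
(simulate/load → filter → normalise → detect → compare → phase statistics
→ optional PSEA/ORA from a GMT file → differential expression) into one
run directory of TSVs plus a manifest; `make_report(out_dir)` produces the
summary tables (rhythmic counts with the Venn partition, DRG class
combinations, the phase-shift summary, lipid class distributions).

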