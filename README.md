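# caflux

Single-cell calcium flux kinetics, dose-response and marker association
for indexed microraft arrays.

## What problem this solves

Parathyroid cells sense extracellular calcium through the calcium-sensing
receptor (CASR); in primary hyperparathyroidism this sensing fails, and a
tumour's cells are heterogeneous in how (and whether) they respond to a
calcium challenge. Given time-lapse Fluo-4 fluorescence stacks of cells
plated on an indexed microraft array (one frame every 5 s for 10 min — a
121-frame stack — at each calcium dose), `caflux`:

1. extracts per-cell **integrated fluorescence above background** per
   frame from the stack and a region label map, and maps each cell to its
   raft grid address;
2. normalizes each trace to its zero time-point (F/F0) and classifies it
   into one of five **kinetic response categories** — maximal,
   rapid/transient, slow, multiple-peak, non-responder — using
   quantitative rules (10% deviation bands, 60-s onset/return windows, a
   2-min slow-rise threshold);
3. fits the proportion of maximal responders versus log calcium dose with
   a **variable-slope four-parameter logistic**

   y(x) = bottom + (top − bottom) / (1 + 10^((log10 EC50 − log10 x)·h)),

   estimating each tumour's **EC50** with a field-resampled bootstrap CI;
4. **segregates a tumour cohort** into two calcium-sensitivity groups by
   the exact optimal 1-D within-group-SSE split, with Welch's test
   between groups;
5. cross-tabulates per-cell **CASR immunofluorescence** positivity
   (isotype-control mean + 3 SD threshold) against binary
   responsiveness, with odds ratio and Fisher's exact test.

A synthetic-data module generates per-class traces, dose-structured cell
populations governed by a known true 4PL, whole cohorts with known group
EC50s, and rendered TIFF stacks with ground-truth label maps, so every
stage is testable without real recordings. It is intended for
investigators quantifying calcium-sensing behaviour in primary
(para)thyroid or other GPCR-driven dose-response assays at single-cell
resolution.

## Worked example

Classify a synthetic rapid/transient trace:

```r
library(caflux)
tr <- simulate_trace(trace_sim_params("rapid_transient"), seed = 2)
str(classify_trace(tr))
#> List of 6
#>  $ label        : chr "rapid_transient"
#>  $ onset_s      : num 20
#>  $ n_peaks      : int 1
#>  $ peak_times_s : num 20
#>  $ plateau_mean : num NA
#>  $ return_time_s: num 65
```

The trace left the +10% baseline band at 20 s (inside the 60-s onset
window) and re-entered it for good at 65 s — within the subsequent 60-s
interval, hence rapid/transient rather than maximal (no sustained
elevated plateau) or multiple-peak (one peak).

Fit and segregate an 11-tumour synthetic cohort (two true EC50 groups at
2.40 and 3.61 mM, 8 doses × 3 fields × 200 cells per tumour):

```r
cfgs <- cohort_two_group_configs(seed = 1)
fits <- lapply(cfgs, function(cf) {
  labs <- do.call(rbind, lapply(cf$dose_series_mM, function(d) {
    s <- simulate_dose_experiment(cf, d, traces = FALSE)
    data.frame(s$meta, label = s$meta$true_class)
  }))
  pts <- aggregate_maximal_proportion(labs)
  bootstrap_ec50_ci(pts, fit_four_pl(pts), n_boot = 1000, seed = cf$seed)
})
fits[[1]]
#> Four-parameter logistic dose-response fit
#>   bottom 0.0662  top 0.9453  hill 3.438
#>   EC50 2.488 mM (log10 0.3959), RSS 0.000575, converged
#>   bootstrap 95% CI: 2.322 - 2.664 mM

ec50 <- vapply(fits, `[[`, numeric(1), "ec50_mM")
segregate_two_groups(ec50, vapply(cfgs, `[[`, "", "sample_id"))
#> Cohort calcium-sensitivity segregation (k = 2)
#>   group 1: n = 6, mean EC50 2.378 mM (95% CI 2.308-2.448)
#>   group 2: n = 5, mean EC50 3.713 mM (95% CI 3.530-3.896)
#>   Welch t = 18.704, p = 4.3e-06
```

Each per-sample fit recovers its generating EC50 to a few percent
(sample 1's true EC50 was drawn near 2.40 mM), and the cohort splits
cleanly into the two generating sensitivity groups.

`run_pipeline(pipeline_config(...))` chains the whole analysis from trace
CSVs (or TIFF stacks + label maps) to a cohort report with per-stage cell
accounting; `inst/scripts/caflux.R` exposes the stages as shell
subcommands (`simulate`, `extract`, `classify`, `fit`, `segregate`,
`associate`, `run`).

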