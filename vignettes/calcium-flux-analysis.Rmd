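---
title: "Single-cell calcium flux kinetics and dose-response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell calcium flux kinetics and dose-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caflux)
```

## The measurement and the model

Parathyroid cells sense extracellular calcium through the calcium-sensing
receptor (CASR) and answer a rise in calcium with a rise in cytosolic free
calcium, visible as increased Fluo-4 fluorescence. `caflux` analyses this
assay at single-cell resolution for cells plated on an indexed microraft
array (50 µm square rafts, 10 µm gaps): time-lapse stacks are acquired at
one frame every 5 s for 10 min (121 frames, the pre-stimulus frame
included) at each extracellular calcium dose, three fields of roughly 200
cells per dose, across a dose series of 0.5, 0.75, 1, 1.25, 2, 3, 5 and
10 mM plus a zero-calcium control.

The analysis chain is:

1. **Trace extraction** — per-frame, per-cell integrated fluorescence
   above background from the stack and a fixed region label map.
2. **Normalization** — each trace is divided by its own frame-0 value
   (F/F0), removing gain and loading differences.
3. **Kinetic classification** — each normalized trace is assigned one of
   five response categories (below).
4. **Dose-response** — the proportion of *maximal* responders per dose is
   fit with a variable-slope four-parameter logistic (4PL) to estimate a
   per-tumour EC50 with a bootstrap confidence interval.
5. **Cohort segregation** — per-sample EC50s are split into two
   calcium-sensitivity groups by an exact 1-D least-squares partition.
6. **Marker association** — per-cell CASR immunofluorescence positivity is
   cross-tabulated against binary responsiveness.

## The five kinetic categories and how the rules are operationalized

The categories are defined by quantitative rules on the normalized trace:
a **maximal** responder rises sharply within the first 60 s and holds a
sustained plateau (within 10%) for the remainder; a **rapid/transient**
responder rises within 60 s and returns to baseline within the following
60 s; a **slow** responder needs more than 2 min of rise before its
plateau; a **multiple-peak** responder shows at least two flux maxima
separated by a return to baseline; a **non-responder** never deviates more
than 10% from baseline.

Several quantities in these rules have no published numeric definition, so
the classifier fixes them explicitly (all user-overridable through
`classification_params()`):

* **Deviation denominators.** "10% deviation" is relative to the reference
  level: baseline deviations are `|x - 1|` (baseline is 1 after
  normalization) and plateau deviations are `|x - L|/L` with `L` the
  terminal plateau level. Relative-to-reference keeps the rules scale
  invariant.
* **"Sharp" onset.** The smoothed trace must leave the +10% baseline band
  within 60 s *and* reach at least half of its eventual maximal excursion
  within that window; the second clause is what separates a sharp rise
  from the early portion of a slow one.
* **"Return to baseline."** Re-entry into the ±10% baseline band sustained
  for at least 2 consecutive frames, guarding against single-frame noise
  crossings.
* **Plateau.** The terminal level `L` is the median of the last 60 s; the
  plateau start is the earliest frame from which the trace stays within
  10% of `L` for the rest of the record (up to 2 stray frames are
  tolerated — residual noise the median filter lets through). A plateau
  must be elevated (`L` above the baseline band) to count as a response.
* **Peaks.** Local maxima of the smoothed trace above the baseline band,
  at least 30 s apart, which also reach at least half the trace's maximal
  excursion. The half-max clause mirrors the sharp-onset rule and stops
  band-edge noise wiggles on a slow rise from being read as extra
  "maxima". Multiple-peak additionally requires a sustained baseline
  return between adjacent peaks.
* **Precedence.** Rules are tested in the order non-responder,
  multiple-peak, rapid/transient, maximal, slow; a trace that leaves the
  band but matches no rule (for instance a single late transient) is
  labelled *ambiguous*, reported separately, and excluded from five-class
  proportions and the responsiveness dichotomy. The five classes are not
  provably exhaustive, so an explicit residual label is more honest than
  forcing a fit.

Classification runs on a 3-frame centered moving median of the normalized
trace; diagnostics (onset, peak times, return time, plateau mean) are
reported on the original 5-s grid.

## Dose-response estimation

For each sample, the pooled proportion of maximal responders at each
positive dose is fit with

$$y(x) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + 10^{(\log_{10}\mathrm{EC50} - \log_{10} x)\,h}},$$

by Levenberg–Marquardt least squares under the box constraints
`0 ≤ bottom, top ≤ 1` and `0.05 ≤ h ≤ 12`, with a deterministic
multi-start grid (data-driven initial values crossed with Hill slopes
0.5–8 and ±0.3 log-unit EC50 offsets) because a steep curve whose EC50
sits near the top of the dose range can trap a single start at the
`top = 1` boundary. Convergence uses function and parameter tolerances of
1e-15; zero-noise data are recovered to machine precision. The
zero-calcium control cannot enter a log-dose fit and is reported
descriptively. Points carry unit weights: per-dose cell numbers are
near-constant (≥ 200 per field) by design.

**Bootstrap EC50 CIs.** The resampling unit is the field-level proportion
within each dose (three fields per dose), refit 1000 times from the
full-data estimates. Two standard small-sample corrections are applied,
because with only three resampling units per dose a naive bootstrap is
anti-conservative: field deviations are rescaled by $\sqrt{m/(m-1)}$ so
the bootstrap variance of each per-dose mean is unbiased, and the
percentile levels are widened from 2.5/97.5 to the t quantile at the
pooled between-field degrees of freedom (Hesterberg's expanded percentile
interval). The package's replicate study (see
`tests/testthat/test-acceptance.R`) measures both the EC50 recovery rate
and the coverage of this interval at study scale. An interval is flagged
unreliable when more than 20% of refits fail.

**Cohort segregation.** The two-group split minimizes total within-group
sum of squares over all contiguous splits of the sorted EC50s (for 1-D
SSE the optimal two-cluster partition is always contiguous, so this
enumeration *is* the exact optimum). A split is "not supported" when the
optimum leaves a singleton group or all EC50s coincide; group 95% CIs are
t-based across samples and the between-group test is Welch's t. No formal
cluster-number inference is attempted beyond this k = 2 versus degenerate
check.

## Marker association

Responsiveness is dichotomized (any of the four responsive classes versus
non-responder), cross-tabulated against marker positivity, and tested
with Fisher's exact test on the pooled 2×2 table — robust to small
per-sample counts; per-sample heterogeneity is reported descriptively as
mean ± SD of the four category proportions across samples. The odds ratio
uses the Haldane +0.5 correction only when a zero cell exists. Marker
positivity is thresholded at mean + 3 SD of per-cell integrated
intensities on isotype-control images; both raw integrated and
area-normalized intensities are emitted, since "intensity per cell" is
ambiguous between the two. The intensity contrast between responsive and
non-responsive cells uses Welch's unequal-variance t.

## What the synthetic generator emulates — and what it does not

Every stage is testable without real data through `simulate_trace()`,
`simulate_dose_experiment()`, `simulate_cohort()` and `render_stack()`.

* **Templates.** Smooth minimal shapes satisfying each class rule:
  saturating exponential rise (maximal), normalized double-exponential
  pulse (rapid/transient; also summed for multiple-peak), re-anchored
  logistic rise (slow), constant baseline (non-responder). Defaults (e.g.
  rise constants of 5–10 s, a 12-s transient decay, a 45-s slow rise
  midpointed at 180 s) are chosen so each noiseless template satisfies its
  rule with margin; no published kinetic constants exist, so these are
  robustness-testing placeholders, not biophysics.
* **Noise.** Multiplicative Gaussian noise (default SD 0.03 of the
  instantaneous value) on post-stimulus frames, reflecting photon-scaled
  variability; frame 0 is the pre-stimulus reference and equals the
  baseline exactly, matching the role of the zero time-point in F/F0
  normalization. Rendered stacks add per-pixel additive Gaussian camera
  noise on a uniform background.
* **Dose structure.** At each dose the probability of the maximal class
  equals a true 4PL (defaults: bottom 0.05, top 0.95, Hill 3 — a typical
  CASR cooperativity); the residual mass is split among the other classes
  with fixed weights (0.60 non-responder, 0.15 rapid/transient, 0.15
  slow, 0.10 multiple-peak), a plausible mid-dose composition chosen
  once. True labels are retained for recovery tests.
* **Cohorts.** `cohort_two_group_configs()` draws 6 + 5 per-sample EC50s
  from N(2.40, 0.02²) and N(3.61, 0.20²) mM; the group SDs are
  back-calculated from t-based 95% CIs of 2.37–2.41 (n = 6) and 3.45–3.95
  (n = 5) mM.
* **Rendering.** Cells are fixed square footprints centred in their rafts
  on a uniform background, scaled so integrated intensity above
  background equals the trace value times a known factor. There is no
  point-spread function, photobleaching, cell morphology, or drift — so
  passing round-trip tests certify the *bookkeeping* (geometry,
  background subtraction, integration, normalization), not robustness to
  real optics.

Because the generator's traces are built from the same conceptual
families the classifier's rules describe, classifier accuracy measured on
them is an internal-consistency check, not an estimate of accuracy on
real recordings, where kinetics are messier and classes blend.

## Problem sizes and numerical choices

The replicate studies run at the study design scale: 8 doses × 3 fields ×
200 cells per tumour, 100 replicate tumours for EC50 recovery and CI
coverage, 500 noisy traces per class for classifier accuracy, and an
11-sample two-group cohort for segregation. Label-level simulation (class
draws from the generating 4PL without rendering each trace) is used for
the 100-replicate studies: the sampling process for per-dose maximal
counts is identical, and it isolates the aggregation → fit → bootstrap
chain from classifier error, which is measured separately. The end-to-end
path through trace simulation, classification and fitting is exercised on
a smaller four-sample cohort.

Degenerate inputs are contracts, not surprises: zero-baseline cells are
excluded with a reason rather than raising batch errors; doses with no
classifiable cells are dropped with a warning; unidentifiable fits
(proportions all on one side of their half-range) and non-positive doses
are rejected; a non-converged fit carries `converged = FALSE` and no CI.

## Known limitations

Regions are fixed across frames (no tracking or drift correction) on the
assumption that motion within 10 min is negligible; there is no automatic
segmentation (label maps are supplied, as regions were marked manually in
the underlying assay); oscillation analysis stops at peak counting; and
the marker analysis treats positivity as binary rather than modelling
intensity as a continuous predictor.
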