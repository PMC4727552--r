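# hand-built traces on the standard 5-s / 600-s grid (121 frames)
grid_times <- seq(0, 600, by = 5)

# piecewise trace builder: value v over [from, to] seconds, baseline 1
piecewise_trace <- function(..., times = grid_times) {
  x <- rep(1, length(times))
  for (seg in list(...))
    x[times >= seg$from & times <= seg$to] <- seg$v
  x
}

step_trace <- function(level = 2, at = 30, times = grid_times)
  ifelse(times >= at, level, 1)

# rise to `peak` at t = at, linear decay back into the baseline band by
# t = back, flat at 1 afterwards
transient_trace <- function(peak = 2, at = 30, back = 90,
                            times = grid_times) {
  x <- rep(1, length(times))
  ramp <- times >= at & times < back
  x[ramp] <- peak - (peak - 1) * (times[ramp] - at) / (back - at)
  x
}

# monotone rise from onset crossing the band early, plateau at `plateau_t`
slow_trace <- function(level = 2, plateau_t = 200, times = grid_times) {
  x <- pmin(1 + (level - 1) * times / plateau_t, level)
  x
}

two_peak_trace <- function(peaks = c(60, 300), level = 2, width = 40,
                           times = grid_times) {
  x <- rep(1, length(times))
  for (p in peaks) {
    tri <- pmax(0, 1 - abs(times - p) / width)
    x <- pmax(x, 1 + (level - 1) * tri)
  }
  x
}

# jittered noisy trace of a given class (uses the generator's per-cell
# parameter draws)
noisy_class_trace <- function(class_label, seed, noise_sd = 0.03) {
  prm <- withr::with_seed(seed,
    caflux:::jitter_params(class_label, noise_sd, 5, 600))
  simulate_trace(prm, seed = seed + 1L)
}

# label table straight from generator ground truth (skips the classifier;
# used to exercise the aggregation/fit chain in isolation)
true_label_table <- function(config) {
  do.call(rbind, lapply(config$dose_series_mM, function(d) {
    s <- simulate_dose_experiment(config, d, traces = FALSE)
    data.frame(s$meta, label = s$meta$true_class)
  }))
}
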