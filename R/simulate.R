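#' Variable-slope four-parameter logistic
#'
#' `y(x) = bottom + (top - bottom) / (1 + 10^((log_ec50 - log10(x)) * hill))`,
#' the standard dose-response model on a log10 concentration axis. At
#' `x = 10^log_ec50` the curve passes through `(top + bottom) / 2` by
#' construction.
#'
#' @param x dose (same units as `10^log_ec50`; here mM), > 0.
#' @param bottom,top lower/upper asymptotes.
#' @param log_ec50 log10 of the EC50.
#' @param hill Hill slope (> 0 for an increasing curve).
#' @return fitted response at `x`.
#' @export
four_pl <- function(x, bottom, top, log_ec50, hill) {
  bottom + (top - bottom) / (1 + 10^((log_ec50 - log10(x)) * hill))
}

# ---- deterministic class templates (normalized units, frame 0 = baseline) ----

# normalized double-exponential pulse: 0 at s <= 0, peak 1
alpha_pulse <- function(s, rise_tau, decay_tau) {
  if (decay_tau <= rise_tau)
    stop("'decay_tau_s' must exceed 'rise_tau_s'")
  s_peak <- (log(decay_tau) - log(rise_tau)) /
    (1 / rise_tau - 1 / decay_tau)
  gmax <- exp(-s_peak / decay_tau) - exp(-s_peak / rise_tau)
  out <- numeric(length(s))
  pos <- s > 0
  out[pos] <- (exp(-s[pos] / decay_tau) - exp(-s[pos] / rise_tau)) / gmax
  out
}

class_template <- function(params, times_s) {
  b <- params$baseline
  A <- params$amplitude * b
  switch(params$class_label,
    non_responder = rep(b, length(times_s)),
    maximal = {
      s <- times_s - params$onset_s
      if (params$rise_tau_s <= 0) {
        b + A * (s >= 0)
      } else {
        b + A * ifelse(s >= 0, 1 - exp(-s / params$rise_tau_s), 0)
      }
    },
    rapid_transient =
      b + A * alpha_pulse(times_s - params$onset_s,
                          params$rise_tau_s, params$decay_tau_s),
    slow = {
      # logistic rise through midpoint onset_s, re-anchored so x(0) = baseline
      sig <- 1 / (1 + exp(-(times_s - params$onset_s) / params$rise_tau_s))
      sig0 <- 1 / (1 + exp(params$onset_s / params$rise_tau_s))
      b + A * (sig - sig0) / (1 - sig0)
    },
    multiple_peak = {
      x <- rep(b, length(times_s))
      for (k in seq_len(params$n_peaks)) {
        onset_k <- params$onset_s + (k - 1) * params$peak_spacing_s
        x <- x + A * alpha_pulse(times_s - onset_k,
                                 params$rise_tau_s, params$decay_tau_s)
      }
      x
    },
    stop("unknown class label")
  )
}

#' Simulate one single-cell calcium flux trace
#'
#' Evaluates the deterministic kinetic template for the requested class
#' on the acquisition grid (frames every `frame_interval_s` over
#' `duration_s`, the initial frame included) and applies multiplicative
#' Gaussian noise to the post-stimulus frames. Frame 0 is the
#' pre-stimulus reference and always equals the baseline, so normalizing
#' to the zero time-point leaves the noiseless template intact.
#'
#' @param params a [trace_sim_params()] object.
#' @param seed integer seed.
#' @return an object of class `flux_trace`: list with `times_s`, `raw`,
#'   `true_class` and the generating `params`.
#' @examples
#' tr <- simulate_trace(trace_sim_params("maximal", noise_sd = 0), seed = 1)
#' range(tr$raw)
#' @export
simulate_trace <- function(params, seed = 1L) {
  stopifnot(inherits(params, "trace_sim_params"))
  n_frames <- as.integer(round(params$duration_s / params$frame_interval_s)) + 1L
  times_s <- (seq_len(n_frames) - 1L) * params$frame_interval_s
  x <- class_template(params, times_s)
  if (params$noise_sd > 0 && n_frames > 1L) {
    eps <- with_seed(seed, rnorm(n_frames - 1L, sd = params$noise_sd))
    x[-1L] <- x[-1L] * (1 + eps)
  }
  structure(list(times_s = times_s, raw = x,
                 true_class = params$class_label, params = params),
            class = "flux_trace")
}

# per-cell jitter of template constants, kept inside ranges where each
# class's rule set is still satisfied with margin
jitter_params <- function(class_label, noise_sd, frame_interval_s, duration_s) {
  def <- class_template_defaults(class_label)
  p <- switch(class_label,
    maximal = list(amplitude = runif(1, 1.2, 2.5),
                   onset_s = runif(1, 5, 35),
                   rise_tau_s = runif(1, 5, 12), decay_tau_s = NULL),
    rapid_transient = list(amplitude = runif(1, 1.2, 1.6),
                           onset_s = runif(1, 5, 30),
                           rise_tau_s = runif(1, 3, 6),
                           decay_tau_s = runif(1, 8, 12)),
    slow = list(amplitude = runif(1, 1.2, 2.0),
                onset_s = runif(1, 160, 220),
                rise_tau_s = runif(1, 38, 55), decay_tau_s = NULL),
    multiple_peak = list(amplitude = runif(1, 1.2, 1.8),
                         onset_s = runif(1, 20, 60),
                         rise_tau_s = runif(1, 3, 7),
                         decay_tau_s = runif(1, 8, 12)),
    non_responder = list(amplitude = NULL, onset_s = NULL,
                         rise_tau_s = NULL, decay_tau_s = NULL)
  )
  trace_sim_params(class_label,
                   amplitude = p$amplitude, onset_s = p$onset_s,
                   rise_tau_s = p$rise_tau_s, decay_tau_s = p$decay_tau_s,
                   n_peaks = if (class_label == "multiple_peak")
                     sample(2:3, 1) else 2L,
                   peak_spacing_s = if (class_label == "multiple_peak")
                     runif(1, 180, 260) else 240,
                   noise_sd = noise_sd,
                   frame_interval_s = frame_interval_s,
                   duration_s = duration_s)
}

#' Simulate the cell population of one field-set at one calcium dose
#'
#' Draws each cell's kinetic class from the mixture implied by the
#' sample's true 4PL at this dose -- `P(maximal)` equals the 4PL value,
#' and the remaining mass is split among the other classes according to
#' `residual_class_weights` -- then (optionally) simulates a noisy trace
#' per cell with per-cell jittered template constants. True labels are
#' retained for recovery testing.
#'
#' @param config a [tumor_sim_config()].
#' @param dose_mM a dose from `config$dose_series_mM`.
#' @param traces if `FALSE`, only class labels and metadata are drawn
#'   (used by large-scale dose-response recovery studies; the label draw
#'   is identical either way).
#' @param noise_sd trace noise SD (default 0.03).
#' @param seed integer seed; defaults to a dose-indexed offset of
#'   `config$seed`.
#' @return a `flux_traces` object: list with `meta` (data.frame:
#'   `sample_id`, `cell_id`, `field`, `dose_mM`, `raft_row`, `raft_col`,
#'   `true_class`), `raw` (cells x frames matrix, `NULL` when
#'   `traces = FALSE`), and `times_s`.
#' @export
simulate_dose_experiment <- function(config, dose_mM, traces = TRUE,
                                     noise_sd = 0.03, seed = NULL) {
  stopifnot(inherits(config, "tumor_sim_config"))
  di <- match(dose_mM, config$dose_series_mM)
  if (is.na(di)) stop("'dose_mM' is not in the config's dose series")
  if (is.null(seed)) seed <- config$seed + 1000L * di

  p_max <- four_pl(dose_mM, config$true_bottom, config$true_top,
                   log10(config$true_ec50_mM), config$true_hill)
  w <- config$residual_class_weights
  if (sum(w) == 0 && p_max < 1)
    stop("residual class weights sum to 0 while P(maximal) < 1")
  n_field <- config$cells_per_field
  n <- n_field * config$fields_per_dose

  with_seed(seed, {
    cls <- sample(c("maximal", names(w)), n, replace = TRUE,
                  prob = c(p_max, (1 - p_max) * w / sum(w)))
    side <- ceiling(sqrt(n_field))
    idx_in_field <- rep(seq_len(n_field), config$fields_per_dose)
    meta <- data.frame(
      sample_id = config$sample_id,
      cell_id = seq_len(n),
      field = rep(seq_len(config$fields_per_dose), each = n_field),
      dose_mM = dose_mM,
      raft_row = (idx_in_field - 1L) %/% side,
      raft_col = (idx_in_field - 1L) %% side,
      true_class = cls,
      stringsAsFactors = FALSE
    )
    raw <- NULL
    times_s <- seq(0, 600, by = 5)
    if (traces) {
      trs <- lapply(seq_len(n), function(i) {
        prm <- jitter_params(cls[i], noise_sd, 5, 600)
        simulate_trace(prm, seed = sample.int(2^30, 1))
      })
      times_s <- trs[[1L]]$times_s
      raw <- do.call(rbind, lapply(trs, `[[`, "raw"))
    }
    structure(list(meta = meta, raw = raw, times_s = times_s),
              class = "flux_traces")
  })
}

#' Simulate a tumour cohort
#'
#' One dose-experiment per sample per dose in each sample's series.
#'
#' @param configs list of [tumor_sim_config()] with unique `sample_id`s.
#' @param traces simulate full traces (see [simulate_dose_experiment()]).
#' @param noise_sd trace noise SD.
#' @return named list (by sample) of named lists (by dose, names
#'   `format(dose)`) of `flux_traces`. Empty input gives an empty list.
#' @export
simulate_cohort <- function(configs, traces = FALSE, noise_sd = 0.03) {
  if (length(configs) == 0L) return(structure(list(), names = character()))
  ids <- vapply(configs, `[[`, "", "sample_id")
  if (anyDuplicated(ids))
    stop("duplicate sample_id in cohort configs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- lapply(configs, function(cf) {
    per_dose <- lapply(cf$dose_series_mM, function(d)
      simulate_dose_experiment(cf, d, traces = traces, noise_sd = noise_sd))
    names(per_dose) <- format(cf$dose_series_mM)
    per_dose
  })
  names(out) <- ids
  out
}

#' Two-group cohort configurations
#'
#' Builds simulation configs for a cohort whose true per-sample EC50s are
#' drawn from two Gaussian groups. Defaults emulate an 11-tumour cohort
#' splitting into a normally calcium-sensitive group (mean 2.40 mM, small
#' spread) and an attenuated group (mean 3.61 mM, wider spread), with the
#' group standard deviations back-calculated from t-based 95% CIs of
#' 2.37-2.41 mM (n = 6) and 3.45-3.95 mM (n = 5).
#'
#' @param n_group1,n_group2 samples per group.
#' @param mean1,sd1,mean2,sd2 group EC50 distributions (mM).
#' @param seed integer seed (also seeds the per-sample configs).
#' @param ... passed to [tumor_sim_config()].
#' @return list of [tumor_sim_config()] objects, with a `true_group`
#'   attribute (1 or 2 per sample).
#' @export
cohort_two_group_configs <- function(n_group1 = 6L, n_group2 = 5L,
                                     mean1 = 2.40, sd1 = 0.02,
                                     mean2 = 3.61, sd2 = 0.20,
                                     seed = 1L, ...) {
  ec50 <- with_seed(seed, c(rnorm(n_group1, mean1, sd1),
                            rnorm(n_group2, mean2, sd2)))
  grp <- rep(1:2, c(n_group1, n_group2))
  configs <- lapply(seq_along(ec50), function(i)
    tumor_sim_config(sample_id = sprintf("PA%02d", i),
                     true_ec50_mM = ec50[i],
                     seed = as.integer(seed + 97L * i), ...))
  attr(configs, "true_group") <- grp
  configs
}
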