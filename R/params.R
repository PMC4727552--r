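#' Kinetic template parameters for one simulated trace
#'
#' Bundles the shape parameters of a single-cell calcium flux template.
#' Defaults are class-specific and chosen so that the noiseless template
#' unambiguously satisfies its class's quantitative definition (see
#' [class_template_defaults()]): e.g. maximal and rapid/transient onsets
#' fall well inside the first 60 s, the slow template needs more than
#' 120 s of rise before plateau, and multi-peak peaks are separated by a
#' baseline return.
#'
#' @param class_label one of [kinetic_classes].
#' @param baseline pre-stimulus normalized intensity (dimensionless; 1.0).
#' @param amplitude fold-change above baseline at the template's maximum
#'   (> 0 for responsive classes; 0 for non-responders).
#' @param onset_s response onset in seconds after stimulus. For the slow
#'   class this is the midpoint of the logistic rise.
#' @param rise_tau_s rise time constant, seconds.
#' @param decay_tau_s decay time constant, seconds (transient/multi-peak).
#' @param n_peaks number of peaks (multi-peak only, >= 2).
#' @param peak_spacing_s spacing between successive peak onsets, seconds.
#' @param noise_sd multiplicative Gaussian noise SD, relative to the
#'   instantaneous intensity (default 0.03).
#' @param frame_interval_s acquisition interval, seconds (default 5).
#' @param duration_s observation period, seconds (default 600, i.e. a
#'   121-frame stack at 5-s intervals).
#' @return an object of class `trace_sim_params`.
#' @export
trace_sim_params <- function(class_label,
                             baseline = 1,
                             amplitude = NULL,
                             onset_s = NULL,
                             rise_tau_s = NULL,
                             decay_tau_s = NULL,
                             n_peaks = 2L,
                             peak_spacing_s = 240,
                             noise_sd = 0.03,
                             frame_interval_s = 5,
                             duration_s = 600) {
  if (length(class_label) != 1L || !class_label %in% kinetic_classes)
    stop("'class_label' must be one of: ",
         paste(kinetic_classes, collapse = ", "))
  if (frame_interval_s <= 0)
    stop("'frame_interval_s' must be positive")
  if (duration_s < 0)
    stop("'duration_s' must be non-negative")

  def <- class_template_defaults(class_label)
  p <- list(
    class_label = class_label,
    baseline = baseline,
    amplitude = if (is.null(amplitude)) def$amplitude else amplitude,
    onset_s = if (is.null(onset_s)) def$onset_s else onset_s,
    rise_tau_s = if (is.null(rise_tau_s)) def$rise_tau_s else rise_tau_s,
    decay_tau_s = if (is.null(decay_tau_s)) def$decay_tau_s else decay_tau_s,
    n_peaks = as.integer(n_peaks),
    peak_spacing_s = peak_spacing_s,
    noise_sd = noise_sd,
    frame_interval_s = frame_interval_s,
    duration_s = duration_s
  )
  if (class_label != "non_responder" && p$amplitude <= 0)
    stop("'amplitude' must be > 0 for responsive classes")
  if (class_label == "non_responder") p$amplitude <- 0
  if (class_label == "multiple_peak" && p$n_peaks < 2L)
    stop("'n_peaks' must be >= 2 for multiple_peak")
  if (p$noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (p$baseline <= 0) stop("'baseline' must be positive")
  structure(p, class = "trace_sim_params")
}

#' Default template constants per kinetic class
#'
#' @param class_label one of [kinetic_classes].
#' @return a list with elements `amplitude`, `onset_s`, `rise_tau_s`,
#'   `decay_tau_s`.
#' @export
class_template_defaults <- function(class_label) {
  switch(class_label,
    maximal         = list(amplitude = 2.0, onset_s = 10,  rise_tau_s = 10, decay_tau_s = NA_real_),
    rapid_transient = list(amplitude = 1.5, onset_s = 15,  rise_tau_s = 5,  decay_tau_s = 12),
    slow            = list(amplitude = 1.5, onset_s = 180, rise_tau_s = 45, decay_tau_s = NA_real_),
    multiple_peak   = list(amplitude = 1.5, onset_s = 30,  rise_tau_s = 5,  decay_tau_s = 12),
    non_responder   = list(amplitude = 0.0, onset_s = NA_real_, rise_tau_s = NA_real_, decay_tau_s = NA_real_),
    stop("unknown class label: ", class_label)
  )
}

#' Simulation configuration for one tumour sample
#'
#' Describes one synthetic tumour: the true four-parameter logistic (4PL)
#' governing the proportion of maximal responders as a function of
#' extracellular calcium, the mixture weights over the remaining kinetic
#' classes, and the experimental design (cells per field, fields per
#' dose, dose series). Defaults mirror the study design: three fields of
#' 200 cells at each of eight calcium concentrations from 0.5 to 10 mM.
#'
#' @param sample_id sample identifier (unique within a cohort).
#' @param true_ec50_mM true EC50 in mM (> 0).
#' @param true_hill true Hill slope (> 0); default 3, a typical
#'   cooperativity for calcium-sensing receptor signalling.
#' @param true_bottom,true_top lower/upper asymptotes of the maximal
#'   responder proportion, `0 <= bottom < top <= 1`.
#' @param residual_class_weights named non-negative weights over the
#'   non-maximal classes used to split the residual probability mass.
#' @param cells_per_field,fields_per_dose design sizes (defaults 200, 3).
#' @param dose_series_mM strictly increasing calcium doses in mM.
#' @param seed integer seed for this sample's draws.
#' @return an object of class `tumor_sim_config`.
#' @export
tumor_sim_config <- function(sample_id,
                             true_ec50_mM,
                             true_hill = 3,
                             true_bottom = 0.05,
                             true_top = 0.95,
                             residual_class_weights = c(non_responder = 0.60,
                                                        rapid_transient = 0.15,
                                                        slow = 0.15,
                                                        multiple_peak = 0.10),
                             cells_per_field = 200L,
                             fields_per_dose = 3L,
                             dose_series_mM = c(0.5, 0.75, 1, 1.25, 2, 3, 5, 10),
                             seed = 1L) {
  stopifnot(length(sample_id) == 1L, nzchar(sample_id))
  if (!(true_bottom >= 0 && true_bottom < true_top && true_top <= 1))
    stop("require 0 <= bottom < top <= 1")
  if (true_ec50_mM <= 0) stop("'true_ec50_mM' must be > 0")
  if (true_hill <= 0) stop("'true_hill' must be > 0")
  if (any(diff(dose_series_mM) <= 0) || any(dose_series_mM <= 0))
    stop("'dose_series_mM' must be strictly increasing and positive")
  if (any(residual_class_weights < 0))
    stop("residual class weights must be >= 0")
  bad <- setdiff(names(residual_class_weights),
                 setdiff(kinetic_classes, "maximal"))
  if (length(bad))
    stop("unknown residual classes: ", paste(bad, collapse = ", "))
  structure(list(
    sample_id = as.character(sample_id),
    true_bottom = true_bottom, true_top = true_top,
    true_ec50_mM = true_ec50_mM, true_hill = true_hill,
    residual_class_weights = residual_class_weights,
    cells_per_field = as.integer(cells_per_field),
    fields_per_dose = as.integer(fields_per_dose),
    dose_series_mM = dose_series_mM,
    seed = as.integer(seed)
  ), class = "tumor_sim_config")
}

#' Microraft grid geometry
#'
#' The plating array is an indexed grid of square rafts: 50 x 50 um
#' culture sites separated by 10 um gaps, so the raft pitch is 60 um.
#' Grid addresses are 0-based `(row, col)` indices obtained by flooring
#' the centroid coordinate divided by the pitch.
#'
#' @param raft_edge_um raft edge length, um (default 50).
#' @param gap_um gap between rafts, um (default 10).
#' @param pixel_size_um physical pixel size, um/pixel.
#' @param n_rows,n_cols grid dimensions in rafts.
#' @return an object of class `grid_geometry` with a derived `pitch_um`.
#' @export
grid_geometry <- function(raft_edge_um = 50, gap_um = 10,
                          pixel_size_um = 1, n_rows = 16L, n_cols = 16L) {
  if (any(c(raft_edge_um, gap_um, pixel_size_um) <= 0) ||
      n_rows <= 0 || n_cols <= 0)
    stop("all geometry dimensions must be positive")
  structure(list(raft_edge_um = raft_edge_um, gap_um = gap_um,
                 pitch_um = raft_edge_um + gap_um,
                 pixel_size_um = pixel_size_um,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
            class = "grid_geometry")
}

#' Kinetic classification parameters
#'
#' Thresholds that operationalize the five class definitions. The 10%
#' deviation bands and the 60-s / 2-min windows follow the published
#' rule set; the remaining values resolve quantities the rules leave
#' open (see the package vignette).
#'
#' @param response_band relative deviation from the reference level below
#'   which a trace is "at" that level (default 0.10).
#' @param onset_window_s window after stimulus within which a "sharp"
#'   onset must occur, seconds (default 60).
#' @param transient_return_window_s maximum time from onset to baseline
#'   return for the rapid/transient class, seconds (default 60).
#' @param slow_rise_min_s minimum rise duration (onset to plateau) for
#'   the slow class, seconds (default 120).
#' @param plateau_band relative deviation tolerated about the plateau
#'   level (default 0.10).
#' @param smooth_window_frames odd moving-median window applied before
#'   rule evaluation (default 3).
#' @param min_peak_separation_s minimum spacing between distinct peaks,
#'   seconds (default 30).
#' @return an object of class `classification_params`.
#' @export
classification_params <- function(response_band = 0.10,
                                  onset_window_s = 60,
                                  transient_return_window_s = 60,
                                  slow_rise_min_s = 120,
                                  plateau_band = 0.10,
                                  smooth_window_frames = 3L,
                                  min_peak_separation_s = 30) {
  if (!(response_band > 0 && response_band < 1) ||
      !(plateau_band > 0 && plateau_band < 1))
    stop("bands must lie in (0, 1)")
  if (any(c(onset_window_s, transient_return_window_s,
            slow_rise_min_s, min_peak_separation_s) <= 0))
    stop("windows must be positive")
  smooth_window_frames <- as.integer(smooth_window_frames)
  if (smooth_window_frames < 1L || smooth_window_frames %% 2L == 0L)
    stop("'smooth_window_frames' must be a positive odd integer")
  structure(list(response_band = response_band,
                 onset_window_s = onset_window_s,
                 transient_return_window_s = transient_return_window_s,
                 slow_rise_min_s = slow_rise_min_s,
                 plateau_band = plateau_band,
                 smooth_window_frames = smooth_window_frames,
                 min_peak_separation_s = min_peak_separation_s),
            class = "classification_params")
}
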