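#' Normalize a raw trace to its zero time-point value
#'
#' Divides every frame by the cell's frame-0 (pre-stimulus) intensity,
#' the F/F0 convention, so the normalized trace starts at exactly 1 and
#' classification is invariant to detector gain.
#'
#' @param raw numeric vector of raw intensities, frame 0 first.
#' @param eps baseline considered zero below this (default 1e-9).
#' @return numeric vector of the same length, or `NULL` with attribute
#'   handling left to [normalize_traces()] when the baseline is zero.
#' @export
normalize_trace <- function(raw, eps = 1e-9) {
  if (length(raw) < 1L) stop("empty trace")
  if (!is.finite(raw[1L]) || raw[1L] <= eps)
    stop("zero baseline: frame-0 intensity <= ", format(eps))
  raw / raw[1L]
}

#' Normalize a matrix of raw traces (cells x frames)
#'
#' Batch form of [normalize_trace()]: cells whose frame-0 intensity is
#' at or below `eps` are excluded with reason `"zero baseline"` rather
#' than raising an error.
#'
#' @param raw numeric matrix, one row per cell, frame 0 in column 1.
#' @param eps zero-baseline threshold.
#' @return list with `normalized` (matrix, excluded rows `NA`) and
#'   `excluded` (data.frame: `row`, `reason`).
#' @export
normalize_traces <- function(raw, eps = 1e-9) {
  stopifnot(is.matrix(raw), ncol(raw) >= 1L)
  f0 <- raw[, 1L]
  bad <- !is.finite(f0) | f0 <= eps
  norm <- raw / f0
  norm[bad, ] <- NA_real_
  list(normalized = norm,
       excluded = data.frame(row = which(bad),
                             reason = rep("zero baseline", sum(bad))))
}

#' Moving-median smoothing
#'
#' Centered running median with shrunken windows at the endpoints
#' (length-preserving); monotone traces stay monotone and isolated
#' single-frame spikes are removed.
#'
#' @param x numeric trace.
#' @param window odd window length in frames, `<= length(x)`.
#' @return smoothed trace of the same length.
#' @export
smooth_trace <- function(x, window = 3L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("'window' must be odd")
  if (window > length(x)) stop("'window' exceeds trace length")
  if (window == 1L || length(x) < 3L) return(x)
  as.numeric(runmed(x, window, endrule = "median"))
}

# first index of a run of >= min_run consecutive TRUEs at or after `from`;
# NA_integer_ if none
first_sustained <- function(ok, from = 1L, min_run = 2L) {
  n <- length(ok)
  if (from > n) return(NA_integer_)
  r <- rle(ok[from:n])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_run)
  if (!length(hit)) return(NA_integer_)
  from + starts[hit[1L]] - 1L
}

# local maxima of s above `level`, thinned to >= min_sep_frames apart
# (greedy by height)
find_peaks <- function(s, level, min_sep_frames) {
  n <- length(s)
  if (n < 3L) return(integer())
  cand <- which(s[-c(1L, n)] > s[-c(n - 1L, n)] &
                s[-c(1L, n)] >= s[-(1:2)]) + 1L
  cand <- cand[s[cand] > level]
  if (length(cand) <= 1L) return(cand)
  keep <- integer()
  for (i in order(s[cand], decreasing = TRUE)) {
    if (all(abs(cand[i] - keep) >= min_sep_frames)) keep <- c(keep, cand[i])
  }
  sort(keep)
}

#' Classify one normalized calcium flux trace
#'
#' Assigns exactly one of the six labels in [kinetic_labels] by applying
#' the quantitative class rules to the median-smoothed trace, in the
#' precedence order non_responder, multiple_peak, rapid_transient,
#' maximal, slow, ambiguous:
#'
#' * **non_responder** -- less than `response_band` (10%) deviation from
#'   baseline at every frame.
#' * **multiple_peak** -- at least two peaks above the baseline band with
#'   a sustained return into the baseline band between them.
#' * **rapid_transient** -- onset (first frame above `1 + response_band`)
#'   within `onset_window_s`, a sustained return to the baseline band
#'   within the subsequent `transient_return_window_s`, and no further
#'   excursion afterwards.
#' * **maximal** -- onset within `onset_window_s`, at least half the
#'   eventual rise reached within that window ("sharp"), and a sustained
#'   elevated plateau (within `plateau_band` of the terminal level for
#'   the rest of the record) achieved within `slow_rise_min_s` of onset.
#' * **slow** -- an elevated plateau achieved only after more than
#'   `slow_rise_min_s` (2 min) of rise.
#' * **ambiguous** -- leaves the baseline band but matches no rule;
#'   reported separately and excluded from five-class proportions.
#'
#' @param normalized numeric normalized trace (frame 0 = 1).
#' @param times_s frame times in seconds, starting at 0.
#' @param params a [classification_params()] object.
#' @return list with `label` and diagnostics `onset_s`, `n_peaks`,
#'   `peak_times_s`, `plateau_mean`, `return_time_s`.
#' @export
classify_trace <- function(normalized, times_s = NULL,
                           params = classification_params()) {
  if (inherits(normalized, "flux_trace")) {
    times_s <- normalized$times_s
    normalized <- normalize_trace(normalized$raw)
  }
  n <- length(normalized)
  if (is.null(times_s)) times_s <- (seq_len(n) - 1L) * 5
  if (length(times_s) != n) stop("times and trace lengths differ")
  dt <- if (n > 1L) times_s[2L] - times_s[1L] else 1
  if (max(times_s) < params$onset_window_s)
    stop("trace shorter than the onset window")

  s <- smooth_trace(normalized, params$smooth_window_frames)
  band <- params$response_band
  diag0 <- list(onset_s = NA_real_, n_peaks = 0L,
                peak_times_s = numeric(), plateau_mean = NA_real_,
                return_time_s = NA_real_)

  in_band <- abs(s - 1) <= band
  if (all(abs(s - 1) < band))
    return(c(list(label = "non_responder"), diag0))

  above <- s > 1 + band
  onset_i <- if (any(above)) which(above)[1L] else NA_integer_
  if (is.na(onset_i))  # leaves the band only downwards: no calcium response
    return(c(list(label = "ambiguous"), diag0))
  onset_s <- times_s[onset_i]

  # peaks must be genuine flux maxima: above the baseline band and
  # reaching at least half the trace's maximal excursion, so noise
  # wiggles near the band edge do not count
  min_sep_frames <- max(1L, ceiling(params$min_peak_separation_s / dt))
  peaks <- find_peaks(s, 1 + band, min_sep_frames)
  peaks <- peaks[s[peaks] >= 1 + 0.5 * (max(s) - 1)]
  diagn <- diag0
  diagn$onset_s <- onset_s
  diagn$n_peaks <- length(peaks)
  diagn$peak_times_s <- times_s[peaks]

  # multiple_peak: adjacent peaks separated by a sustained baseline return
  if (length(peaks) >= 2L) {
    for (k in seq_len(length(peaks) - 1L)) {
      mid <- seq(peaks[k], peaks[k + 1L])
      if (!is.na(first_sustained(in_band[mid])))
        return(c(list(label = "multiple_peak"), diagn))
    }
  }

  # rapid_transient: early onset, sustained return soon after, quiet tail
  ret_i <- first_sustained(in_band, from = onset_i)
  if (!is.na(ret_i)) diagn$return_time_s <- times_s[ret_i]
  if (onset_s <= params$onset_window_s && !is.na(ret_i) &&
      times_s[ret_i] - onset_s <= params$transient_return_window_s &&
      all(abs(s[ret_i:n] - 1) < band))
    return(c(list(label = "rapid_transient"), diagn))

  # elevated terminal plateau: suffix staying within plateau_band of the
  # terminal level (median of the last 60 s)
  tail_i <- which(times_s >= max(times_s) - 60)
  level <- median(s[tail_i])
  plateau_i <- NA_integer_
  if (level > 1 + band) {
    in_plat <- abs(s - level) / level <= params$plateau_band
    # tolerate up to 2 stray frames in the suffix (residual noise the
    # median smoother let through), but the plateau must start in band
    stray <- rev(cumsum(rev(!in_plat)))
    suffix_ok <- stray <= 2L & in_plat
    if (any(suffix_ok)) plateau_i <- which(suffix_ok)[1L]
  }
  if (!is.na(plateau_i)) {
    diagn$plateau_mean <- mean(s[plateau_i:n])
    rise_s <- times_s[plateau_i] - onset_s
    half_rise <- 1 + 0.5 * (max(s) - 1)
    sharp <- onset_s <= params$onset_window_s &&
      any(s[times_s <= params$onset_window_s] >= half_rise)
    if (sharp && rise_s <= params$slow_rise_min_s)
      return(c(list(label = "maximal"), diagn))
    if (rise_s > params$slow_rise_min_s)
      return(c(list(label = "slow"), diagn))
    return(c(list(label = "ambiguous"), diagn))
  }
  c(list(label = "ambiguous"), diagn)
}

#' Classify a batch of traces
#'
#' Normalizes (F/F0) and classifies every row of a raw trace matrix or a
#' `flux_traces` object. Cells with a zero frame-0 baseline are excluded
#' with a reason instead of raising an error.
#'
#' @param traces a `flux_traces` object (from [simulate_dose_experiment()]
#'   or [read_traces_csv()]) or a raw numeric matrix (cells x frames).
#' @param params a [classification_params()].
#' @param times_s frame times (only needed for bare matrices).
#' @return data.frame with the metadata columns (when available) plus
#'   `label`, `onset_s`, `n_peaks`, `plateau_mean`, `return_time_s`,
#'   `excluded_reason`.
#' @export
classify_traces <- function(traces, params = classification_params(),
                            times_s = NULL) {
  if (inherits(traces, "flux_traces")) {
    meta <- traces$meta
    raw <- traces$raw
    times_s <- traces$times_s
  } else {
    raw <- as.matrix(traces)
    meta <- data.frame(cell_id = seq_len(nrow(raw)))
  }
  if (is.null(raw)) stop("no trace data to classify")
  if (is.null(times_s)) times_s <- (seq_len(ncol(raw)) - 1L) * 5
  nt <- normalize_traces(raw)
  out <- data.frame(meta,
                    label = NA_character_, onset_s = NA_real_,
                    n_peaks = NA_integer_, plateau_mean = NA_real_,
                    return_time_s = NA_real_,
                    excluded_reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(raw))) {
    if (i %in% nt$excluded$row) {
      out$excluded_reason[i] <- "zero baseline"
      next
    }
    cl <- classify_trace(nt$normalized[i, ], times_s, params)
    out$label[i] <- cl$label
    out$onset_s[i] <- cl$onset_s
    out$n_peaks[i] <- cl$n_peaks
    out$plateau_mean[i] <- cl$plateau_mean
    out$return_time_s[i] <- cl$return_time_s
  }
  out
}

#' Summarize kinetic class composition
#'
#' Counts and proportions of the five kinetic classes per group
#' (by default sample x dose). Ambiguous and excluded cells are reported
#' separately and do not enter the five-class proportions, which sum
#' to 1 within each group.
#'
#' @param labels data.frame from [classify_traces()].
#' @param by grouping columns present in `labels` (default
#'   `c("sample_id", "dose_mM")`, intersected with available columns).
#' @return data.frame with one row per group: `n_total` (five-class
#'   cells), `n_<class>` counts, `p_<class>` proportions, `n_ambiguous`,
#'   `n_excluded`.
#' @export
summarize_classes <- function(labels, by = c("sample_id", "dose_mM")) {
  if (nrow(labels) == 0L) stop("no classified cells to summarize")
  by <- intersect(by, names(labels))
  key <- if (length(by)) interaction(labels[by], drop = TRUE, sep = "\r")
         else factor(rep("all", nrow(labels)))
  groups <- split(seq_len(nrow(labels)), key)
  rows <- lapply(groups, function(idx) {
    lab <- labels$label[idx]
    counts <- vapply(kinetic_classes, function(k)
      sum(lab == k, na.rm = TRUE), integer(1))
    n_total <- sum(counts)
    props <- if (n_total > 0) counts / n_total else rep(NA_real_, 5)
    g <- if (length(by)) labels[idx[1L], by, drop = FALSE]
         else data.frame(row.names = 1L)
    cbind(g,
          data.frame(n_total = n_total,
                     as.list(setNames(counts, paste0("n_", kinetic_classes))),
                     as.list(setNames(props, paste0("p_", kinetic_classes))),
                     n_ambiguous = sum(lab == "ambiguous", na.rm = TRUE),
                     n_excluded = sum(is.na(lab))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Indicator-loading quality control via a calcium ionophore
#'
#' Cells are challenged with an ionophore (e.g. ionomycin) after the
#' primary observation period; any cell whose post-ionophore trace never
#' exceeds the response band is flagged "indicator-invalid" (failed dye
#' loading or depleted stores) and should be excluded from summaries.
#'
#' @param primary_norm,post_norm normalized trace vectors or matrices
#'   (cells x frames) on a shared baseline. `post_norm = NULL` skips QC
#'   with a warning and returns `NA`.
#' @param params a [classification_params()]; the pass threshold is
#'   `1 + response_band` on the smoothed post-ionophore trace.
#' @return logical vector, `TRUE` = pass.
#' @export
ionophore_qc <- function(primary_norm, post_norm,
                         params = classification_params()) {
  if (is.null(post_norm)) {
    warning("no post-ionophore traces: QC skipped")
    n <- if (is.matrix(primary_norm)) nrow(primary_norm) else 1L
    return(rep(NA, n))
  }
  if (!is.matrix(post_norm)) post_norm <- matrix(post_norm, nrow = 1L)
  apply(post_norm, 1L, function(x)
    any(smooth_trace(x, params$smooth_window_frames) >
          1 + params$response_band))
}
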