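#' Expected frame count of a time-lapse stack
#'
#' Acquisition at one frame every `interval_s` for `duration_s`,
#' including the initial pre-stimulus frame:
#' `duration_s / interval_s + 1`. The standard protocol (one frame
#' every 5 s for 10 min) gives 121 frames; input stacks are validated
#' against this.
#'
#' @param duration_s observation period, seconds.
#' @param interval_s frame interval, seconds; must divide the duration.
#' @return integer frame count.
#' @examples
#' expected_frame_count(600, 5)  # 121
#' @export
expected_frame_count <- function(duration_s, interval_s) {
  if (interval_s <= 0) stop("'interval_s' must be positive")
  if (duration_s < 0) stop("'duration_s' must be non-negative")
  k <- duration_s / interval_s
  if (abs(k - round(k)) > 1e-9)
    stop("'interval_s' does not divide 'duration_s'")
  as.integer(round(k)) + 1L
}

#' Pipeline configuration
#'
#' A single document holding every tunable of a run, so paper-gap
#' decisions (bands, windows, thresholds) are user-overridable in one
#' place. Input mode is either `"traces"` (per-sample trace CSVs, see
#' [read_traces_csv()]) or `"stacks"` (per-sample, per-dose TIFF stack +
#' label-map pairs).
#'
#' @param samples list of per-sample entries. For mode `"traces"`:
#'   `list(sample_id =, traces_csv =, markers_csv = NULL)`. For mode
#'   `"stacks"`: `list(sample_id =, stacks = list(list(dose_mM =,
#'   field =, stack_tif =, labels_tif =)), markers_csv = NULL)`.
#' @param mode `"traces"` or `"stacks"`.
#' @param dose_series_mM dose manifest in mM; 0 denotes the zero-calcium
#'   control (excluded from the log-dose fit, reported descriptively).
#' @param classification a [classification_params()].
#' @param n_boot bootstrap refits per sample CI.
#' @param seed integer master seed.
#' @param out_dir output directory (`NULL` = no files written).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(samples, mode = c("traces", "stacks"),
                            dose_series_mM = c(0, 0.5, 0.75, 1, 1.25, 2, 3, 5, 10),
                            classification = classification_params(),
                            n_boot = 1000L, seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  if (anyDuplicated(dose_series_mM)) stop("doses must be unique")
  ids <- vapply(samples, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample_id")
  structure(list(mode = mode, samples = samples,
                 dose_series_mM = dose_series_mM,
                 classification = classification,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

load_sample_traces <- function(entry, mode) {
  if (mode == "traces") return(read_traces_csv(entry$traces_csv))
  parts <- lapply(entry$stacks, function(st) {
    frames <- read_stack_tiff(st$stack_tif)
    labels <- read_labels_tiff(st$labels_tif)
    tr <- integrated_intensity(frames, labels)
    tr$meta$sample_id <- entry$sample_id
    tr$meta$dose_mM <- st$dose_mM
    tr$meta$field <- if (is.null(st$field)) 1L else st$field
    tr
  })
  meta <- do.call(rbind, lapply(parts, `[[`, "meta"))
  meta$cell_id <- seq_len(nrow(meta))  # unique across stacks
  structure(list(meta = meta,
                 raw = do.call(rbind, lapply(parts, `[[`, "raw")),
                 times_s = parts[[1L]]$times_s),
            class = "flux_traces")
}

#' Run the full analysis pipeline
#'
#' Executes, per sample: load traces (or extract them from stacks) ->
#' normalize -> classify -> summarize per dose and field -> aggregate
#' maximal proportions -> 4PL fit with bootstrap EC50 CI; then cohort
#' segregation across samples and, where marker tables are supplied, the
#' marker x responsiveness association. A failing sample is recorded and
#' the run continues; results are fully reproducible given the config
#' seed, and every written table carries the config hash in the report.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `run_report`: `fits` (per-sample
#'   [fit_four_pl()] results), `segregation`, `association` (or `NULL`),
#'   `summaries`, `cohort_table`, `counts` (per-sample loaded /
#'   excluded / ambiguous / classified), `zero_dose` (descriptive
#'   proportions at the zero-calcium control), `errors`, `config_hash`,
#'   `version`, `seed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  fits <- list(); summaries <- list(); counts <- list()
  zero_dose <- list(); errors <- list()
  marker_pool <- list()
  for (i in seq_along(config$samples)) {
    entry <- config$samples[[i]]
    sid <- entry$sample_id
    res <- tryCatch({
      traces <- load_sample_traces(entry, config$mode)
      labels <- classify_traces(traces, config$classification)
      n_loaded <- nrow(labels)
      n_excluded <- sum(!is.na(labels$excluded_reason))
      n_classified <- sum(!is.na(labels$label))
      stopifnot(n_loaded == n_classified + n_excluded)  # conservation
      summ <- summarize_classes(labels, by = c("sample_id", "dose_mM"))
      pts <- aggregate_maximal_proportion(labels)
      zd <- pts[pts$dose_mM <= 0, , drop = FALSE]
      fit_pts <- pts[pts$dose_mM > 0, , drop = FALSE]
      fit <- fit_four_pl(fit_pts)
      if (fit$converged)
        fit <- bootstrap_ec50_ci(fit_pts, fit, n_boot = config$n_boot,
                                 seed = config$seed + 13L * i)
      if (!is.null(out_dir)) {
        write_table_csv(labels[setdiff(names(labels), "field_props")],
                        file.path(out_dir, paste0(sid, "_labels.csv")))
        write_table_csv(summ, file.path(out_dir, paste0(sid, "_summary.csv")))
        write_fit_json(fit, file.path(out_dir, paste0(sid, "_fit.json")))
      }
      if (!is.null(entry$markers_csv)) {
        mk <- as.data.frame(data.table::fread(entry$markers_csv))
        joined <- merge(labels[c("cell_id", "label")],
                        mk[c("cell_id", "positive")], by = "cell_id")
        marker_pool[[sid]] <- data.frame(
          sample_id = sid, marker = as.logical(joined$positive),
          responsive = binarize_responsiveness(joined$label))
      }
      list(fit = fit, summ = summ, zd = zd,
           cnt = data.frame(sample_id = sid, loaded = n_loaded,
                            excluded = n_excluded,
                            ambiguous = sum(labels$label == "ambiguous",
                                            na.rm = TRUE),
                            classified = n_classified))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[sid]] <- conditionMessage(res)
    } else {
      fits[[sid]] <- res$fit
      summaries[[sid]] <- res$summ
      counts[[sid]] <- res$cnt
      if (nrow(res$zd)) zero_dose[[sid]] <- res$zd
    }
  }

  ec50 <- vapply(fits, function(f)
    if (isTRUE(f$converged)) f$ec50_mM else NA_real_, numeric(1))
  ok <- !is.na(ec50)
  segregation <- if (sum(ok) >= 4L)
    segregate_two_groups(ec50[ok], names(ec50)[ok]) else NULL

  association <- NULL
  if (length(marker_pool)) {
    pool <- do.call(rbind, marker_pool)
    association <- cross_tabulate(pool$marker, pool$responsive,
                                  pool$sample_id)
  }

  cohort_table <- do.call(rbind, lapply(names(fits), function(sid) {
    f <- fits[[sid]]
    ci <- f$ec50_ci_95
    data.frame(sample_id = sid, ec50_mM = f$ec50_mM,
               ci_low = if (is.null(ci)) NA_real_ else ci[1L],
               ci_high = if (is.null(ci)) NA_real_ else ci[2L],
               converged = f$converged,
               group = NA_integer_, stringsAsFactors = FALSE)
  }))
  if (!is.null(segregation) && !is.null(cohort_table)) {
    mi <- match(cohort_table$sample_id, segregation$table$sample_id)
    cohort_table$group <- segregation$table$group[mi]
  }

  report <- structure(list(
    fits = fits, segregation = segregation, association = association,
    summaries = summaries, cohort_table = cohort_table,
    counts = do.call(rbind, counts), zero_dose = zero_dose,
    errors = errors, config_hash = config_hash(config),
    version = as.character(packageVersion("caflux")),
    seed = config$seed), class = "run_report")

  if (!is.null(out_dir)) {
    if (!is.null(cohort_table))
      write_table_csv(cohort_table, file.path(out_dir, "cohort.csv"))
    if (!is.null(association))
      jsonlite::write_json(
        list(counts = association$counts,
             proportions = as.list(association$proportions),
             odds_ratio = association$odds_ratio,
             p_value = association$p_value),
        file.path(out_dir, "association.json"),
        auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(config_hash = report$config_hash, version = report$version,
           seed = report$seed, errors = errors,
           counts = report$counts),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("caflux run report (", length(x$fits), " samples, config ",
      substr(x$config_hash, 1, 8), ")\n", sep = "")
  if (!is.null(x$cohort_table)) print(x$cohort_table)
  if (!is.null(x$segregation)) print(x$segregation)
  if (!is.null(x$association)) print(x$association)
  if (length(x$errors))
    cat("sample errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
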