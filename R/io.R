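#' Write / read per-cell trace tables as CSV
#'
#' One row per cell with metadata columns followed by trace columns
#' `t0...tN` (frame index order, 5-s grid by default). Numeric values
#' are written with 17 significant digits so a write/read round trip is
#' lossless for doubles, and repeated writes of the same table are
#' byte-identical.
#'
#' @param traces a `flux_traces` object.
#' @param path output CSV path.
#' @return `read_traces_csv` returns a `flux_traces` object.
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(inherits(traces, "flux_traces"))
  raw <- traces$raw
  colnames(raw) <- paste0("t", seq_len(ncol(raw)) - 1L)
  df <- cbind(traces$meta, as.data.frame(raw))
  write_csv17(df, path)
  invisible(path)
}

#' @rdname write_traces_csv
#' @param frame_interval_s frame interval used to reconstruct `times_s`.
#' @export
read_traces_csv <- function(path, frame_interval_s = 5) {
  df <- as.data.frame(data.table::fread(path))
  tcols <- grep("^t[0-9]+$", names(df), value = TRUE)
  tcols <- tcols[order(as.integer(sub("^t", "", tcols)))]
  if (!length(tcols)) stop("no trace columns t0...tN in ", path)
  raw <- as.matrix(df[tcols])
  dimnames(raw) <- NULL
  structure(list(meta = df[setdiff(names(df), tcols)],
                 raw = raw,
                 times_s = (seq_along(tcols) - 1L) * frame_interval_s),
            class = "flux_traces")
}

# CSV writer with full double precision (%.17g); deterministic bytes
write_csv17 <- function(df, path) {
  cols <- lapply(df, function(v) {
    if (is.double(v)) sprintf("%.17g", v) else as.character(v)
  })
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Write a plain data.frame as CSV (full precision, deterministic)
#'
#' @param df data.frame (list-columns are flattened to
#'   semicolon-separated strings).
#' @param path output path.
#' @export
write_table_csv <- function(df, path) {
  df <- as.data.frame(df)
  is_list <- vapply(df, is.list, logical(1))
  df[is_list] <- lapply(df[is_list], function(col)
    vapply(col, function(v)
      paste(sprintf("%.17g", v), collapse = ";"),
      character(1)))
  write_csv17(df, path)
}

#' Serialize a 4PL fit to / from JSON
#'
#' @param fit a `four_pl_fit`.
#' @param path file path.
#' @return `read_fit_json` returns a list of fit fields.
#' @export
write_fit_json <- function(fit, path) {
  x <- list(bottom = fit$bottom, top = fit$top, log_ec50 = fit$log_ec50,
            hill = fit$hill, ec50_mM = fit$ec50_mM, rss = fit$rss,
            converged = fit$converged, n_points = fit$n_points)
  if (!is.null(fit$ec50_ci_95))
    x$ec50_ci_95 <- list(low = fit$ec50_ci_95[1L],
                         high = fit$ec50_ci_95[2L],
                         n_bootstrap = attr(fit$ec50_ci_95, "n_bootstrap"),
                         unreliable = attr(fit$ec50_ci_95, "unreliable"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
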