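#' Render synthetic traces into a time-lapse image stack
#'
#' Paints each cell as a fixed square footprint centred in its raft, on
#' a uniform background. At frame t the footprint's per-pixel value is
#' `background_level + trace_t * intensity_scale / footprint_area`, so
#' the integrated intensity above background of the region equals
#' `trace_t * intensity_scale` exactly; optional additive Gaussian
#' camera noise is applied per pixel per frame. A matching integer label
#' map assigns every painted pixel its cell id.
#'
#' @param traces a `flux_traces` object with `raft_row`/`raft_col` in
#'   its `meta` (one raft per cell).
#' @param geometry a [grid_geometry()] large enough to hold every
#'   address.
#' @param background_level uniform background intensity (default 100).
#' @param camera_noise_sd additive Gaussian camera noise SD (default 0).
#' @param intensity_scale integrated intensity corresponding to a trace
#'   value of 1 (default 1000).
#' @param footprint_px side of the square cell footprint in pixels;
#'   must fit within one raft.
#' @param seed seed for camera noise.
#' @return an object of class `time_lapse_stack`: list with `frames`
#'   (list of matrices), `labels` (integer matrix), `times_s`,
#'   `intensity_scale`, `background_level`, `meta`.
#' @export
render_stack <- function(traces, geometry, background_level = 100,
                         camera_noise_sd = 0, intensity_scale = 1000,
                         footprint_px = 4L, seed = 1L) {
  stopifnot(inherits(traces, "flux_traces"), inherits(geometry, "grid_geometry"))
  meta <- traces$meta
  if (is.null(meta$raft_row) || is.null(meta$raft_col))
    stop("traces carry no raft addresses")
  if (anyDuplicated(meta[c("raft_row", "raft_col")]))
    stop("two traces mapped to the same raft: overlapping footprints")
  if (any(meta$raft_row < 0 | meta$raft_row >= geometry$n_rows |
          meta$raft_col < 0 | meta$raft_col >= geometry$n_cols))
    stop("raft address outside the grid")
  px <- geometry$pixel_size_um
  pitch_px <- geometry$pitch_um / px
  H <- ceiling(geometry$n_rows * pitch_px)
  W <- ceiling(geometry$n_cols * pitch_px)
  footprint_px <- as.integer(footprint_px)
  if (footprint_px < 1L || footprint_px * px > geometry$raft_edge_um)
    stop("footprint does not fit within one raft")

  labels <- matrix(0L, H, W)
  pix <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    # footprint centred in the raft
    r0 <- floor(meta$raft_row[i] * pitch_px +
                  (geometry$raft_edge_um / px - footprint_px) / 2) + 1L
    c0 <- floor(meta$raft_col[i] * pitch_px +
                  (geometry$raft_edge_um / px - footprint_px) / 2) + 1L
    rows <- r0:(r0 + footprint_px - 1L)
    cols <- c0:(c0 + footprint_px - 1L)
    cells <- as.matrix(expand.grid(rows, cols))
    idx <- cells[, 1L] + (cells[, 2L] - 1L) * H
    if (any(labels[idx] != 0L)) stop("overlapping footprints")
    id <- if (!is.null(meta$cell_id)) meta$cell_id[i] else i
    labels[idx] <- as.integer(id)
    pix[[i]] <- idx
  }
  n_frames <- ncol(traces$raw)
  area <- footprint_px^2
  frames <- with_seed(seed, lapply(seq_len(n_frames), function(t) {
    fr <- matrix(background_level, H, W)
    for (i in seq_len(nrow(meta)))
      fr[pix[[i]]] <- background_level +
        traces$raw[i, t] * intensity_scale / area
    if (camera_noise_sd > 0)
      fr <- fr + matrix(rnorm(H * W, sd = camera_noise_sd), H, W)
    fr
  }))
  structure(list(frames = frames, labels = labels,
                 times_s = traces$times_s,
                 intensity_scale = intensity_scale,
                 background_level = background_level,
                 meta = meta),
            class = "time_lapse_stack")
}

#' Write / read a multi-page 16-bit grayscale TIFF stack
#'
#' Frames are stored one per page as 16-bit grayscale; intensities are
#' divided by `max_dn` on write and multiplied back on read, so values
#' must lie in `[0, max_dn]` and are quantized to integer DN.
#'
#' @param frames list of numeric matrices (or a `time_lapse_stack`).
#' @param path file path.
#' @param max_dn full-scale digital number (default 65535).
#' @return `read_stack_tiff` returns a list of numeric matrices.
#' @export
write_stack_tiff <- function(frames, path, max_dn = 65535) {
  frames <- as_frame_list(frames)
  if (any(vapply(frames, function(f) any(f < 0 | f > max_dn), logical(1))))
    stop("intensities outside [0, max_dn]")
  tiff::writeTIFF(lapply(frames, function(f) f / max_dn), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, max_dn = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) round(p * max_dn))
}

#' Write / read an integer region label map as single-page TIFF
#'
#' @param labels integer matrix (labels < 65536).
#' @param path file path.
#' @return `read_labels_tiff` returns an integer matrix.
#' @export
write_labels_tiff <- function(labels, path) {
  if (any(labels < 0L) || any(labels > 65535L))
    stop("labels must lie in [0, 65535]")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_labels_tiff
#' @export
read_labels_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
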