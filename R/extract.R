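#' Per-frame background level
#'
#' The background of a frame is the median intensity over all pixels not
#' assigned to any cell region (label 0). The median is robust to the
#' bright cell-adjacent halo that would bias a mean.
#'
#' @param frame numeric matrix (one image frame).
#' @param labels integer label matrix of the same dimensions; 0 =
#'   background.
#' @return scalar background level.
#' @export
estimate_background <- function(frame, labels) {
  if (!all(dim(frame) == dim(labels)))
    stop("frame and label map dimensions differ")
  bg <- frame[labels == 0L]
  if (length(bg) == 0L)
    stop("label map covers the entire frame: no background pixels")
  median(bg)
}

#' Integrated intensity above background per cell region per frame
#'
#' For each labelled region k and frame t, sums `max(pixel - background_t,
#' 0)` over the region's pixels, where `background_t` is the per-frame
#' median of unlabelled pixels. Regions are fixed across frames (no
#' tracking); negative background-subtracted pixels are clamped at zero.
#'
#' @param stack a 3-D numeric array (rows x cols x frames), a list of
#'   frame matrices, or a `time_lapse_stack` from [render_stack()] /
#'   [read_stack_tiff()].
#' @param labels integer label matrix (0 = background, k > 0 = cell k).
#' @param frame_interval_s acquisition interval, seconds.
#' @return a `flux_traces` object whose `meta` holds `cell_id` and
#'   `area` (pixels) and whose `raw` matrix holds the per-frame
#'   integrated intensities (one row per cell). Empty label maps yield
#'   zero rows with a warning.
#' @export
integrated_intensity <- function(stack, labels, frame_interval_s = 5) {
  frames <- as_frame_list(stack)
  if (!all(dim(frames[[1L]]) == dim(labels)))
    stop("stack and label map dimensions differ")
  ids <- sort(unique(labels[labels > 0L]))
  times_s <- (seq_along(frames) - 1L) * frame_interval_s
  if (length(ids) == 0L) {
    warning("empty label map: no cell regions")
    return(structure(list(
      meta = data.frame(cell_id = integer(), area = integer()),
      raw = matrix(numeric(), nrow = 0L, ncol = length(frames)),
      times_s = times_s), class = "flux_traces"))
  }
  lab_vec <- as.integer(labels)
  in_cell <- lab_vec > 0L
  fac <- factor(lab_vec[in_cell], levels = ids)
  area <- as.integer(table(fac))
  raw <- vapply(frames, function(fr) {
    bg <- estimate_background(fr, labels)
    v <- pmax(as.numeric(fr)[in_cell] - bg, 0)
    as.numeric(rowsum(v, fac))
  }, numeric(length(ids)))
  raw <- matrix(raw, nrow = length(ids))
  structure(list(meta = data.frame(cell_id = ids, area = area),
                 raw = raw, times_s = times_s),
            class = "flux_traces")
}

as_frame_list <- function(stack) {
  if (inherits(stack, "time_lapse_stack")) stack <- stack$frames
  if (is.array(stack) && length(dim(stack)) == 3L)
    return(lapply(seq_len(dim(stack)[3L]), function(t) stack[, , t]))
  if (is.list(stack)) return(stack)
  if (is.matrix(stack)) return(list(stack))
  stop("unsupported stack representation")
}

#' Map cell regions to raft grid addresses
#'
#' Computes each region's intensity-free centroid (mean of its pixel
#' centers, pixel (0,0) at top-left) in micrometres and assigns the
#' 0-based raft address `floor(centroid_um / pitch_um)` per axis, where
#' the pitch is raft edge + gap. Centroids exactly on a gap midline go to
#' the higher-index raft (floor convention); centroids outside the grid
#' extent are flagged and left unaddressed.
#'
#' @param labels integer label matrix.
#' @param geometry a [grid_geometry()].
#' @return data.frame: `cell_id`, `centroid_x_um`, `centroid_y_um`,
#'   `raft_row`, `raft_col`, `in_bounds`.
#' @export
map_regions_to_rafts <- function(labels, geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  ids <- sort(unique(labels[labels > 0L]))
  px <- geometry$pixel_size_um
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  # pixel centers: pixel (0,0) spans [0, px) x [0, px)
  y_um <- (idx[, 1L] - 0.5) * px
  x_um <- (idx[, 2L] - 0.5) * px
  cy <- tapply(y_um, factor(lab, levels = ids), mean)
  cx <- tapply(x_um, factor(lab, levels = ids), mean)
  row <- floor(cy / geometry$pitch_um)
  col <- floor(cx / geometry$pitch_um)
  in_bounds <- row >= 0 & row < geometry$n_rows &
               col >= 0 & col < geometry$n_cols
  row[!in_bounds] <- NA_real_
  col[!in_bounds] <- NA_real_
  data.frame(cell_id = ids,
             centroid_x_um = as.numeric(cx), centroid_y_um = as.numeric(cy),
             raft_row = as.integer(row), raft_col = as.integer(col),
             in_bounds = as.logical(in_bounds))
}

#' Raft address of a point coordinate
#'
#' @param x_um,y_um coordinates in micrometres.
#' @param geometry a [grid_geometry()].
#' @return data.frame with `raft_row`, `raft_col` (0-based).
#' @export
raft_address <- function(x_um, y_um, geometry) {
  data.frame(raft_row = as.integer(floor(y_um / geometry$pitch_um)),
             raft_col = as.integer(floor(x_um / geometry$pitch_um)))
}

#' Per-cell marker immunofluorescence quantification
#'
#' Background-subtracted marker intensity summed over each cell region
#' (integrated intensity), plus the area-normalized mean. A cell is
#' scored marker-positive when its integrated intensity exceeds a
#' threshold set from isotype-control measurements: mean + 3 SD of the
#' per-cell integrated intensities on the control image(s).
#'
#' @param image numeric matrix, marker channel.
#' @param labels integer label matrix aligned with `image`.
#' @param control_images list of isotype-control images (each a matrix)
#'   measured with `control_labels`; required unless `threshold` given.
#' @param control_labels label matrix for the control images (defaults
#'   to `labels`).
#' @param threshold explicit positivity threshold on integrated
#'   intensity (overrides the control-derived one).
#' @param saturation_dn detector full-scale value; regions containing a
#'   saturated pixel are flagged (default 65535, 16-bit).
#' @return data.frame: `cell_id`, `area`, `marker_intensity` (integrated),
#'   `marker_mean_intensity` (per pixel), `threshold`, `positive`,
#'   `saturated`.
#' @export
measure_marker_intensity <- function(image, labels, control_images = NULL,
                                     control_labels = labels,
                                     threshold = NULL,
                                     saturation_dn = 65535) {
  rec <- integrated_intensity(list(image), labels, frame_interval_s = 1)
  if (is.null(threshold)) {
    if (is.null(control_images) || length(control_images) == 0L)
      stop("positivity thresholding requires control images or an ",
           "explicit threshold")
    ctrl <- unlist(lapply(control_images, function(im)
      integrated_intensity(list(im), control_labels,
                           frame_interval_s = 1)$raw[, 1L]))
    threshold <- mean(ctrl) + 3 * sd(ctrl)
    if (is.na(threshold)) threshold <- mean(ctrl)  # single control cell
  }
  sat <- vapply(rec$meta$cell_id, function(k)
    any(image[labels == k] >= saturation_dn), logical(1))
  data.frame(cell_id = rec$meta$cell_id,
             area = rec$meta$area,
             marker_intensity = rec$raw[, 1L],
             marker_mean_intensity = rec$raw[, 1L] / rec$meta$area,
             threshold = threshold,
             positive = rec$raw[, 1L] > threshold,
             saturated = sat)
}
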