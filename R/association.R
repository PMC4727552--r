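#' Binary responsiveness from a kinetic class label
#'
#' A cell is calcium-responsive if it shows any flux response: maximal,
#' rapid/transient, slow or multiple-peak. Non-responders are
#' non-responsive; ambiguous cells are excluded (`NA`).
#'
#' @param label character vector of [kinetic_labels].
#' @return logical vector (`NA` for ambiguous or missing labels).
#' @export
binarize_responsiveness <- function(label) {
  out <- rep(NA, length(label))
  out[label %in% setdiff(kinetic_classes, "non_responder")] <- TRUE
  out[label %in% "non_responder"] <- FALSE
  out
}

#' Cross-tabulate marker status against calcium responsiveness
#'
#' Pools per-cell marker positivity (e.g. CASR immunofluorescence above
#' the isotype-control threshold) and binary responsiveness into a 2x2
#' table, with the derived proportions reported in this kind of assay:
#' marker-negative among responsive cells, marker-positive among
#' non-responsive cells, and marker-positive among responsive cells.
#' The odds ratio is `(a*d)/(b*c)` (Haldane +0.5 correction only when a
#' zero cell exists) and association is tested by Fisher's exact test.
#' When sample identifiers are supplied, a per-sample table of the four
#' category proportions with mean and SD across samples is included.
#'
#' @param marker logical per-cell marker positivity.
#' @param responsive logical per-cell responsiveness (from
#'   [binarize_responsiveness()]); `NA` pairs are dropped and counted.
#' @param sample_id optional per-cell sample identifiers.
#' @return an object of class `cross_tab`: `counts` (2x2 matrix, rows
#'   marker +/-, cols responsive +/-), `n`, `n_excluded`, `proportions`
#'   (named: `marker_neg_among_responsive`,
#'   `marker_pos_among_nonresponsive`, `marker_pos_among_responsive`),
#'   `odds_ratio`, `p_value`, and optionally `per_sample` with
#'   `mean_sd`.
#' @export
cross_tabulate <- function(marker, responsive, sample_id = NULL) {
  if (length(marker) != length(responsive))
    stop("flag vectors differ in length")
  if (length(marker) == 0L) stop("empty input")
  keep <- !is.na(marker) & !is.na(responsive)
  n_excluded <- sum(!keep)
  m <- marker[keep]; r <- responsive[keep]
  if (!length(m)) stop("no complete marker/responsiveness pairs")
  a <- sum(m & r);  b <- sum(!m & r)
  c_ <- sum(m & !r); d <- sum(!m & !r)
  counts <- matrix(c(a, b, c_, d), 2L, 2L,
                   dimnames = list(marker = c("pos", "neg"),
                                   responsive = c("yes", "no")))
  props <- c(
    marker_neg_among_responsive = if (a + b > 0) b / (a + b) else NA_real_,
    marker_pos_among_nonresponsive = if (c_ + d > 0) c_ / (c_ + d) else NA_real_,
    marker_pos_among_responsive = if (a + b > 0) a / (a + b) else NA_real_
  )
  hald <- if (any(counts == 0L)) 0.5 else 0
  or <- ((a + hald) * (d + hald)) / ((b + hald) * (c_ + hald))
  p <- fisher.test(counts)$p.value
  out <- list(counts = counts, n = length(m), n_excluded = n_excluded,
              proportions = props, odds_ratio = or, p_value = p)
  if (!is.null(sample_id)) {
    sid <- sample_id[keep]
    per <- do.call(rbind, lapply(split(seq_along(m), sid), function(idx) {
      mm <- m[idx]; rr <- r[idx]; nn <- length(idx)
      data.frame(sample_id = sid[idx[1L]], n = nn,
                 pos_responsive = sum(mm & rr) / nn,
                 pos_nonresponsive = sum(mm & !rr) / nn,
                 neg_responsive = sum(!mm & rr) / nn,
                 neg_nonresponsive = sum(!mm & !rr) / nn,
                 stringsAsFactors = FALSE)
    }))
    rownames(per) <- NULL
    cats <- c("pos_responsive", "pos_nonresponsive",
              "neg_responsive", "neg_nonresponsive")
    out$per_sample <- per
    out$mean_sd <- data.frame(category = cats,
                              mean = vapply(per[cats], mean, numeric(1)),
                              sd = vapply(per[cats], sd, numeric(1)))
  }
  structure(out, class = "cross_tab")
}

#' @export
print.cross_tab <- function(x, ...) {
  cat("Marker x responsiveness cross-tabulation (n = ", x$n, ")\n", sep = "")
  print(x$counts)
  cat(sprintf("  marker-neg among responsive: %.1f%%\n",
              100 * x$proportions[["marker_neg_among_responsive"]]))
  cat(sprintf("  marker-pos among non-responsive: %.1f%%\n",
              100 * x$proportions[["marker_pos_among_nonresponsive"]]))
  cat(sprintf("  odds ratio %.3f, Fisher exact p = %.3g\n",
              x$odds_ratio, x$p_value))
  invisible(x)
}

#' Compare marker intensity between responsive and non-responsive cells
#'
#' Per-group mean, SD, n and t-based 95% CI of a per-cell intensity
#' (e.g. integrated CASR immunofluorescence), with a Welch
#' unequal-variance two-sample t-test between the groups.
#'
#' @param intensity numeric per-cell intensities.
#' @param responsive logical per-cell responsiveness; `NA` pairs dropped.
#' @return an object of class `intensity_comparison`: `groups`
#'   (data.frame with rows responsive/non-responsive: `n`, `mean`, `sd`,
#'   `ci_low`, `ci_high`), `statistic`, `df`, `p_value`,
#'   `mean_difference`. If a group has fewer than 2 cells the test is
#'   unset with a warning.
#' @export
compare_intensity_by_response <- function(intensity, responsive) {
  keep <- !is.na(intensity) & !is.na(responsive)
  x <- intensity[keep & responsive]
  y <- intensity[keep & !responsive]
  gstats <- function(v) {
    ci <- t_ci(v)
    data.frame(n = length(v), mean = mean(v), sd = sd(v),
               ci_low = ci[1L], ci_high = ci[2L])
  }
  groups <- rbind(responsive = gstats(x), non_responsive = gstats(y))
  if (length(x) < 2L || length(y) < 2L) {
    warning("fewer than 2 cells in a group: comparison unset")
    return(structure(list(groups = groups, statistic = NA_real_,
                          df = NA_real_, p_value = NA_real_,
                          mean_difference = mean(x) - mean(y)),
                     class = "intensity_comparison"))
  }
  tt <- t.test(x, y)
  structure(list(groups = groups, statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 mean_difference = mean(x) - mean(y)),
            class = "intensity_comparison")
}

#' @export
print.intensity_comparison <- function(x, ...) {
  cat("Marker intensity by responsiveness\n")
  print(round(x$groups, 4))
  cat(sprintf("  Welch t = %.3f (df %.1f), p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
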