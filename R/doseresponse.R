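#' Maximal-responder proportion per dose
#'
#' Aggregates per-cell kinetic labels into one dose-response point per
#' sample per dose: the pooled proportion of cells in the maximal class
#' among all five-class cells, plus the per-field proportions kept for
#' bootstrap resampling. Ambiguous and excluded cells do not count.
#' The zero-calcium control, if present, contributes a point like any
#' other; [fit_four_pl()] rejects non-positive doses, so exclude it from
#' the fit set (it is reported descriptively by the pipeline).
#'
#' @param labels data.frame from [classify_traces()] with columns
#'   `sample_id`, `dose_mM`, `field`, `label`.
#' @return data.frame of class `dose_response_points`: `sample_id`,
#'   `dose_mM`, `n_cells`, `n_maximal`, `proportion`, and a list-column
#'   `field_props`. Doses with no classifiable cells are dropped with a
#'   warning.
#' @export
aggregate_maximal_proportion <- function(labels) {
  need <- c("sample_id", "dose_mM", "label")
  if (!all(need %in% names(labels)))
    stop("labels need columns: ", paste(need, collapse = ", "))
  if (is.null(labels$field)) labels$field <- 1L
  keep <- !is.na(labels$label) & labels$label %in% kinetic_classes
  key <- interaction(labels$sample_id, labels$dose_mM, drop = TRUE, sep = "\r")
  rows <- lapply(split(seq_len(nrow(labels)), key), function(idx) {
    sub <- labels[idx, ]
    ok <- keep[idx]
    n_cells <- sum(ok)
    if (n_cells == 0L) return(NULL)
    fp <- vapply(split(sub$label[ok] == "maximal", sub$field[ok]),
                 mean, numeric(1))
    data.frame(sample_id = sub$sample_id[1L], dose_mM = sub$dose_mM[1L],
               n_cells = n_cells,
               n_maximal = sum(sub$label[ok] == "maximal"),
               proportion = sum(sub$label[ok] == "maximal") / n_cells,
               field_props = I(list(unname(fp))))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L)
    warning(dropped, " dose point(s) dropped: no classifiable cells")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no dose points with classifiable cells")
  out <- out[order(out$sample_id, out$dose_mM), ]
  rownames(out) <- NULL
  class(out) <- c("dose_response_points", "data.frame")
  out
}

# Levenberg-Marquardt 4PL least squares with box constraints; par order
# c(bottom, top, log_ec50, hill)
fit_4pl_core <- function(dose, prop, starts, lower, upper) {
  resid_fn <- function(par)
    four_pl(dose, par[1L], par[2L], par[3L], par[4L]) - prop
  best <- NULL
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-15, ptol = 1e-15, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(f)) next
    sse <- sum(f$fvec^2)
    if (is.null(best) || sse < best$sse)
      best <- list(par = f$par, sse = sse, info = f$info)
  }
  best
}

#' Fit a variable-slope four-parameter logistic dose-response curve
#'
#' Constrained least squares of the pooled maximal-responder proportion
#' against log10 calcium concentration under the model of [four_pl()],
#' with `0 <= bottom, top <= 1` box constraints and deterministic
#' multi-start (a data-driven initial value plus Hill-slope and EC50
#' perturbations) to avoid local minima. Unit weights are used: per-dose
#' cell numbers are near-constant by design.
#'
#' @param points a `dose_response_points` data.frame (or any data.frame
#'   with `dose_mM` and `proportion`); needs >= 4 points, all doses > 0,
#'   and proportions on both sides of their half-range.
#' @param hill_max upper box constraint on the Hill slope (default 12).
#' @return an object of class `four_pl_fit`: `bottom`, `top`,
#'   `log_ec50`, `hill`, `ec50_mM`, `rss`, `converged`, `n_points`,
#'   `points`, `ec50_ci_95` (`NULL` until [bootstrap_ec50_ci()]).
#' @export
fit_four_pl <- function(points, hill_max = 12) {
  dose <- points$dose_mM
  prop <- points$proportion
  if (length(dose) < 4L) stop("need at least 4 dose points")
  if (any(dose <= 0)) stop("non-positive dose in fit set (exclude the ",
                           "zero-calcium control before fitting)")
  half <- (min(prop) + max(prop)) / 2
  if (!any(prop < half) || !any(prop > half))
    stop("proportions do not bracket their half-range; curve not ",
         "identifiable")
  lx <- log10(dose)
  lower <- c(0, 0, min(lx) - 2, 0.05)
  upper <- c(1, 1, max(lx) + 2, hill_max)
  le0 <- lx[which.min(abs(prop - half))]
  base <- c(max(0, min(prop)), min(1, max(prop)), le0, 1)
  starts <- list()
  for (h in c(0.5, 1, 2, 4, 8))
    for (dle in c(-0.3, 0, 0.3))
      starts[[length(starts) + 1L]] <-
        replace(replace(base, 3L, le0 + dle), 4L, h)
  best <- fit_4pl_core(dose, prop, starts, lower, upper)
  if (is.null(best))
    return(structure(list(bottom = NA_real_, top = NA_real_,
                          log_ec50 = NA_real_, hill = NA_real_,
                          ec50_mM = NA_real_, rss = NA_real_,
                          converged = FALSE, n_points = length(dose),
                          points = points, ec50_ci_95 = NULL),
                     class = "four_pl_fit"))
  par <- best$par
  structure(list(bottom = par[1L], top = par[2L], log_ec50 = par[3L],
                 hill = par[4L], ec50_mM = 10^par[3L], rss = best$sse,
                 converged = best$info %in% 1:4 && par[1L] < par[2L],
                 n_points = length(dose), points = points,
                 ec50_ci_95 = NULL),
            class = "four_pl_fit")
}

#' @export
print.four_pl_fit <- function(x, ...) {
  cat("Four-parameter logistic dose-response fit\n")
  cat(sprintf("  bottom %.4f  top %.4f  hill %.3f\n",
              x$bottom, x$top, x$hill))
  cat(sprintf("  EC50 %.4g mM (log10 %.4f), RSS %.3g, %s\n",
              x$ec50_mM, x$log_ec50, x$rss,
              if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$ec50_ci_95))
    cat(sprintf("  bootstrap 95%% CI: %.4g - %.4g mM%s\n",
                x$ec50_ci_95[1L], x$ec50_ci_95[2L],
                if (isTRUE(attr(x$ec50_ci_95, "unreliable")))
                  " (unreliable)" else ""))
  invisible(x)
}

#' Predict from a 4PL fit
#'
#' @param object a `four_pl_fit`.
#' @param dose_mM doses at which to evaluate the fitted curve.
#' @param ... ignored.
#' @return fitted proportions.
#' @export
predict.four_pl_fit <- function(object, dose_mM, ...) {
  four_pl(dose_mM, object$bottom, object$top, object$log_ec50, object$hill)
}

#' Bootstrap percentile confidence interval for the EC50
#'
#' Resamples the three field-level proportions within each dose (with
#' replacement), refits the 4PL to the resampled per-dose means (fields
#' have equal cell numbers by design, so the mean of field proportions
#' is the pooled proportion), and takes a percentile interval of the
#' resulting EC50s. Two standard small-sample corrections are applied,
#' because with only three fields per dose the naive bootstrap is
#' anti-conservative: field deviations are rescaled by
#' `sqrt(m/(m-1))` so the bootstrap variance of each per-dose mean is
#' unbiased, and the percentile levels are widened to the t quantile at
#' the pooled between-field degrees of freedom (Hesterberg's expanded
#' percentile interval). If more than 20% of refits fail to converge
#' the interval is flagged unreliable.
#'
#' @param points `dose_response_points` with a `field_props` list-column.
#' @param fit a converged [fit_four_pl()] result (its estimates seed the
#'   refits).
#' @param n_boot number of bootstrap refits (default 1000).
#' @param seed integer seed.
#' @return the `fit` with `ec50_ci_95` filled: numeric `(low, high)` mM,
#'   attributes `n_bootstrap` and `unreliable`.
#' @export
bootstrap_ec50_ci <- function(points, fit, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(fit, "four_pl_fit"))
  if (!isTRUE(fit$converged)) stop("cannot bootstrap a non-converged fit")
  if (is.null(points$field_props))
    stop("points carry no field-level proportions")
  dose <- points$dose_mM
  lx <- log10(dose)
  lower <- c(0, 0, min(lx) - 2, 0.05)
  upper <- c(1, 1, max(lx) + 2, 12)
  st0 <- pmin(pmax(c(fit$bottom, fit$top, fit$log_ec50, fit$hill), lower),
              upper)
  # rescale field deviations by sqrt(m/(m-1)): with few fields per dose
  # the naive bootstrap variance of the mean is biased low by (m-1)/m,
  # and this standard correction makes it unbiased
  fp <- lapply(points$field_props, function(v) {
    m <- length(v)
    if (m < 2L) v else mean(v) + (v - mean(v)) * sqrt(m / (m - 1))
  })
  ec <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    prop_b <- vapply(fp, function(v) mean(sample(v, replace = TRUE)),
                     numeric(1))
    best <- fit_4pl_core(dose, prop_b, list(st0), lower, upper)
    if (is.null(best) || !best$info %in% 1:4 || best$par[1L] >= best$par[2L])
      return(NA_real_)
    10^best$par[3L]
  }, numeric(1)))
  fail_rate <- mean(is.na(ec))
  # expanded percentile levels (Hesterberg): with few resampling units
  # the plain 2.5/97.5 percentiles undercover, so widen the levels to
  # the t quantile at the pooled between-field degrees of freedom
  df_fields <- sum(vapply(points$field_props, length, integer(1)) - 1L)
  a <- if (df_fields > 0) pnorm(-qt(0.975, df_fields)) else 0.025
  ci <- unname(quantile(ec, c(a, 1 - a), na.rm = TRUE))
  attr(ci, "n_bootstrap") <- n_boot
  attr(ci, "unreliable") <- fail_rate > 0.20
  fit$ec50_ci_95 <- ci
  fit
}

#' Segregate a cohort's EC50s into two calcium-sensitivity groups
#'
#' Exact optimal two-group split in one dimension: over the sorted
#' per-sample EC50s, every contiguous split is enumerated and the one
#' minimizing the total within-group sum of squares is chosen (for 1-D
#' SSE the optimal two-cluster partition is always contiguous). Group
#' means, t-based 95% CIs across samples, and a Welch two-sample test
#' between groups are reported. The split is declared "not supported"
#' when the optimum leaves fewer than two samples in a group or the
#' EC50s are all identical (every split has zero SSE).
#'
#' @param ec50s numeric per-sample EC50s (>= 4 samples).
#' @param sample_ids optional identifiers (defaults to `S1..Sn`).
#' @return an object of class `cohort_segregation`: `supported`, `table`
#'   (per-sample `sample_id`, `ec50_mM`, `group`), `group_means`,
#'   `group_ci_95` (2 x 2), `statistic`, `p_value`, `sse`.
#' @export
segregate_two_groups <- function(ec50s, sample_ids = NULL) {
  n <- length(ec50s)
  if (n < 4L) stop("need at least 4 samples to segregate")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  ord <- order(ec50s)
  x <- ec50s[ord]
  sse_of <- function(v) sum((v - mean(v))^2)
  splits <- seq_len(n - 1L)
  sse <- vapply(splits, function(k)
    sse_of(x[seq_len(k)]) + sse_of(x[(k + 1L):n]), numeric(1))
  k_best <- splits[which.min(sse)]
  degenerate <- diff(range(x)) == 0
  supported <- !degenerate && k_best >= 2L && (n - k_best) >= 2L

  tab <- data.frame(sample_id = sample_ids, ec50_mM = ec50s,
                    group = NA_integer_, stringsAsFactors = FALSE)
  if (!supported) {
    tab$group <- 1L
    return(structure(list(supported = FALSE, table = tab,
                          group_means = mean(ec50s),
                          group_ci_95 = t_ci(ec50s),
                          statistic = NA_real_, p_value = NA_real_,
                          sse = min(sse)),
                     class = "cohort_segregation"))
  }
  grp_sorted <- rep(1:2, c(k_best, n - k_best))
  tab$group[ord] <- grp_sorted
  g1 <- x[seq_len(k_best)]
  g2 <- x[(k_best + 1L):n]
  tt <- t.test(g2, g1)  # Welch by default
  structure(list(supported = TRUE, table = tab,
                 group_means = c(mean(g1), mean(g2)),
                 group_ci_95 = rbind(t_ci(g1), t_ci(g2)),
                 statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 sse = sse[which.min(sse)]),
            class = "cohort_segregation")
}

t_ci <- function(v, level = 0.95) {
  n <- length(v)
  if (n < 2L) return(c(NA_real_, NA_real_))
  half <- qt(1 - (1 - level) / 2, n - 1L) * sd(v) / sqrt(n)
  c(mean(v) - half, mean(v) + half)
}

#' @export
print.cohort_segregation <- function(x, ...) {
  cat("Cohort calcium-sensitivity segregation (k = 2)\n")
  if (!x$supported) {
    cat("  two-group split NOT supported; single-group mean EC50 ",
        sprintf("%.3f mM\n", x$group_means[1L]), sep = "")
    return(invisible(x))
  }
  for (g in 1:2)
    cat(sprintf("  group %d: n = %d, mean EC50 %.3f mM (95%% CI %.3f-%.3f)\n",
                g, sum(x$table$group == g), x$group_means[g],
                x$group_ci_95[g, 1L], x$group_ci_95[g, 2L]))
  cat(sprintf("  Welch t = %.3f, p = %.3g\n", x$statistic, x$p_value))
  invisible(x)
}
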