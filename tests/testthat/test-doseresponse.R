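test_that("maximal proportions aggregate with per-field detail", {
  lab <- data.frame(sample_id = "s", dose_mM = 2,
                    field = rep(1:2, each = 100),
                    label = c(rep("maximal", 50), rep("non_responder", 50),
                              rep("maximal", 30), rep("slow", 70)))
  pts <- aggregate_maximal_proportion(lab)
  expect_equal(pts$n_cells, 200L)
  expect_equal(pts$proportion, 80 / 200)
  expect_equal(pts$field_props[[1]], c(0.5, 0.3))

  all_max <- data.frame(sample_id = "s", dose_mM = 1, field = 1,
                        label = rep("maximal", 10))
  expect_equal(aggregate_maximal_proportion(all_max)$proportion, 1)

  # a dose with only unclassifiable cells is dropped with a warning
  mixed <- rbind(all_max,
                 data.frame(sample_id = "s", dose_mM = 3, field = 1,
                            label = rep("ambiguous", 5)))
  expect_warning(pts2 <- aggregate_maximal_proportion(mixed), "dropped")
  expect_equal(pts2$dose_mM, 1)
})

test_that("pooled proportion at the top asymptote matches the generator", {
  cfg <- tumor_sim_config("t", true_ec50_mM = 1, true_top = 0.9, seed = 17)
  labs <- true_label_table(cfg)
  pts <- aggregate_maximal_proportion(labs)
  p10 <- pts$proportion[pts$dose_mM == 10]
  p_true <- four_pl(10, 0.05, 0.9, 0, 3)
  expect_lt(abs(p10 - p_true), 3 * sqrt(p_true * (1 - p_true) / 600))
})

test_that("noiseless 4PL data are refit exactly", {
  doses <- c(0.5, 1, 2, 4, 8)
  pts <- data.frame(dose_mM = doses,
                    proportion = four_pl(doses, 0, 1, log10(2), 2))
  f <- fit_four_pl(pts)
  expect_true(f$converged)
  expect_equal(f$bottom, 0, tolerance = 1e-6)
  expect_equal(f$top, 1, tolerance = 1e-6)
  expect_equal(f$ec50_mM, 2, tolerance = 1e-6)
  expect_equal(f$hill, 2, tolerance = 1e-6)
  # the fitted curve passes through the half-range at the EC50
  expect_equal(predict(f, f$ec50_mM), (f$top + f$bottom) / 2,
               tolerance = 1e-9)
})

test_that("the fit is invariant to point order and duplication", {
  doses <- c(0.5, 0.75, 1, 1.25, 2, 3, 5, 10)
  set.seed(3)
  prop <- pmin(pmax(four_pl(doses, 0.05, 0.95, log10(2.4), 3) +
                      rnorm(8, 0, 0.02), 0), 1)
  pts <- data.frame(dose_mM = doses, proportion = prop)
  f1 <- fit_four_pl(pts)
  f2 <- fit_four_pl(pts[sample(8), ])
  expect_equal(f1$ec50_mM, f2$ec50_mM, tolerance = 1e-8)
  f3 <- fit_four_pl(rbind(pts, pts))
  expect_equal(f1$ec50_mM, f3$ec50_mM, tolerance = 1e-6)
})

test_that("fitted curves with positive hill increase monotonically", {
  set.seed(12)
  for (i in 1:10) {
    tru <- c(runif(1, 0, 0.2), runif(1, 0.8, 1), log10(runif(1, 1, 5)),
             runif(1, 0.5, 4))
    doses <- c(0.5, 0.75, 1, 1.25, 2, 3, 5, 10)
    pts <- data.frame(dose_mM = doses,
                      proportion = four_pl(doses, tru[1], tru[2], tru[3], tru[4]))
    f <- fit_four_pl(pts)
    grid <- seq(0.2, 20, length.out = 200)
    expect_true(all(diff(predict(f, grid)) > 0))
  }
})

test_that("degenerate or unidentifiable inputs are rejected", {
  expect_error(fit_four_pl(data.frame(dose_mM = c(1, 2, 3),
                                      proportion = c(0.1, 0.5, 0.9))),
               "at least 4")
  expect_error(fit_four_pl(data.frame(dose_mM = c(0, 1, 2, 3),
                                      proportion = c(0, 0.1, 0.5, 0.9))),
               "non-positive dose")
  expect_error(fit_four_pl(data.frame(dose_mM = c(1, 2, 4, 8),
                                      proportion = rep(0.5, 4))),
               "half-range")
})

test_that("bootstrap CIs are deterministic and collapse on identical fields", {
  doses <- c(0.5, 0.75, 1, 1.25, 2, 3, 5, 10)
  prop <- four_pl(doses, 0.05, 0.95, log10(2.4), 3)
  pts <- data.frame(dose_mM = doses, proportion = prop)
  pts$field_props <- I(lapply(prop, function(p) rep(p, 3)))
  class(pts) <- c("dose_response_points", "data.frame")
  f <- fit_four_pl(pts)
  f1 <- bootstrap_ec50_ci(pts, f, n_boot = 50, seed = 5)
  f2 <- bootstrap_ec50_ci(pts, f, n_boot = 50, seed = 5)
  expect_identical(f1$ec50_ci_95, f2$ec50_ci_95)
  # identical fields -> every resample refits the same curve
  expect_lt(diff(f1$ec50_ci_95), 1e-6)
  expect_true(f1$ec50_ci_95[1] <= f$ec50_mM && f$ec50_mM <= f1$ec50_ci_95[2])
  expect_error(bootstrap_ec50_ci(pts, structure(list(converged = FALSE),
                                                class = "four_pl_fit"), 10, 1),
               "non-converged")
})

test_that("two-group segregation matches arithmetic and brute force", {
  ec <- c(2.38, 2.40, 2.41, 3.50, 3.61, 3.72)
  seg <- segregate_two_groups(ec)
  expect_true(seg$supported)
  expect_equal(seg$table$group, c(1, 1, 1, 2, 2, 2))
  expect_equal(seg$group_means, c(mean(ec[1:3]), mean(ec[4:6])))
  expect_equal(seg$group_means, c(2.396667, 3.61), tolerance = 1e-6)
  expect_lt(seg$group_means[1], seg$group_means[2])

  # degenerate: identical EC50s cannot support a split
  seg0 <- segregate_two_groups(c(2.4, 2.4, 2.4, 2.4))
  expect_false(seg0$supported)

  expect_error(segregate_two_groups(c(1, 2, 3)), "at least 4")

  # brute-force enumeration of contiguous splits agrees on random cohorts
  brute <- function(x) {
    ord <- sort(x)
    sse <- sapply(1:(length(x) - 1), function(k)
      sum((ord[1:k] - mean(ord[1:k]))^2) +
        sum((ord[(k + 1):length(x)] - mean(ord[(k + 1):length(x)]))^2))
    min(sse)
  }
  set.seed(10)
  for (i in 1:25) {
    x <- runif(sample(4:12, 1), 1, 5)
    seg <- segregate_two_groups(x)
    expect_equal(seg$sse, brute(x), tolerance = 1e-12)
  }
})

test_that("a two-group cohort is segregated with zero misassignments", {
  cfgs <- cohort_two_group_configs(seed = 2026)
  truth <- attr(cfgs, "true_group")
  # recover each sample's EC50 from generator-labelled populations
  ec <- vapply(cfgs, function(cf)
    fit_four_pl(aggregate_maximal_proportion(true_label_table(cf)))$ec50_mM,
    numeric(1))
  seg <- segregate_two_groups(ec, vapply(cfgs, `[[`, "", "sample_id"))
  expect_true(seg$supported)
  expect_identical(seg$table$group, truth)
  expect_lt(seg$p_value, 1e-4)
  expect_equal(seg$group_means[1], 2.40, tolerance = 0.05)
  expect_equal(seg$group_means[2], 3.61, tolerance = 0.15)
})
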