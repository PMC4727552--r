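test_that("normalization divides by the zero time-point", {
  expect_equal(normalize_trace(c(100, 200, 300)), c(1, 2, 3))
  expect_equal(normalize_trace(rep(50, 10)), rep(1, 10))
  expect_error(normalize_trace(c(0, 5, 5)), "zero baseline")

  # batch form excludes instead of erroring
  raw <- rbind(c(100, 150), c(0, 10), c(2, 4))
  nt <- normalize_traces(raw)
  expect_equal(nt$excluded$row, 2L)
  expect_equal(nt$excluded$reason, "zero baseline")
  expect_equal(nt$normalized[3, ], c(1, 2))
  expect_true(all(is.na(nt$normalized[2, ])))
})

test_that("moving-median smoothing kills spikes, preserves structure", {
  expect_equal(smooth_trace(c(1, 10, 1), 3), c(1, 1, 1))
  expect_equal(smooth_trace(rep(2.5, 9), 3), rep(2.5, 9))
  mono <- cumsum(runif(30))
  expect_true(all(diff(smooth_trace(mono, 3)) >= 0))
  expect_error(smooth_trace(1:10, 4), "odd")
  expect_error(smooth_trace(1:3, 5), "length")
})

test_that("each class rule labels its defining prototype", {
  expect_identical(classify_trace(rep(1, 121), grid_times)$label,
                   "non_responder")

  res <- classify_trace(step_trace(2, 30), grid_times)
  expect_identical(res$label, "maximal")
  expect_equal(res$onset_s, 30)
  expect_equal(res$plateau_mean, 2, tolerance = 1e-6)

  res <- classify_trace(transient_trace(2, 30, 90), grid_times)
  expect_identical(res$label, "rapid_transient")
  expect_lte(res$return_time_s - res$onset_s, 60)

  res <- classify_trace(slow_trace(2, 200), grid_times)
  expect_identical(res$label, "slow")

  res <- classify_trace(two_peak_trace(c(60, 300)), grid_times)
  expect_identical(res$label, "multiple_peak")
  expect_equal(res$n_peaks, 2L)

  expect_error(classify_trace(c(1, 1.5), c(0, 5)), "shorter")
})

test_that("every trace receives exactly one label (exhaustiveness)", {
  set.seed(77)
  for (i in 1:400) {
    x <- pmax(0.05, 1 + cumsum(rnorm(121, 0, 0.05)))
    lab <- classify_trace(x / x[1], grid_times)$label
    expect_true(lab %in% kinetic_labels)
  }
})

test_that("classification is scale-invariant and deterministic", {
  set.seed(55)
  for (i in 1:50) {
    cl <- sample(kinetic_classes, 1)
    tr <- noisy_class_trace(cl, seed = 1000 + i)
    lab1 <- classify_traces(matrix(tr$raw, 1))$label
    gain <- runif(1, 0.01, 100)
    lab2 <- classify_traces(matrix(gain * tr$raw, 1))$label
    expect_identical(lab1, lab2)
    expect_identical(lab1, classify_traces(matrix(tr$raw, 1))$label)
  }
})

test_that("widening the response band only moves cells toward non_responder", {
  set.seed(66)
  traces <- lapply(1:60, function(i)
    noisy_class_trace(sample(kinetic_classes, 1), seed = 2000 + i))
  for (bands in list(c(0.05, 0.10), c(0.10, 0.20))) {
    nr <- lapply(bands, function(b) {
      p <- classification_params(response_band = b)
      vapply(traces, function(tr)
        classify_trace(normalize_trace(tr$raw), tr$times_s, p)$label ==
          "non_responder", logical(1))
    })
    expect_true(all(nr[[2]][nr[[1]]]))  # superset at the wider band
  }
})

test_that("noisy generated traces are recovered at >= 95% per class", {
  acc <- vapply(kinetic_classes, function(cl) {
    hits <- vapply(1:200, function(i) {
      tr <- noisy_class_trace(cl, seed = i * 13 + match(cl, kinetic_classes))
      classify_trace(tr)$label == cl
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(acc >= 0.95))
})

test_that("class summaries count and normalize correctly", {
  lab <- data.frame(sample_id = "s", dose_mM = 2,
                    label = c(rep("maximal", 3), "non_responder"))
  s <- summarize_classes(lab)
  expect_equal(s$n_total, 4L)
  expect_equal(s$p_maximal, 0.75)
  expect_equal(s$p_non_responder, 0.25)
  expect_equal(s$p_maximal + s$p_non_responder + s$p_slow +
                 s$p_rapid_transient + s$p_multiple_peak, 1)

  one <- summarize_classes(data.frame(sample_id = "s", dose_mM = 1,
                                      label = rep("slow", 5)))
  expect_equal(one$p_slow, 1)
  expect_equal(one$p_maximal, 0)

  # ambiguous cells are excluded from the five-class proportions
  amb <- summarize_classes(data.frame(sample_id = "s", dose_mM = 1,
                                      label = c("maximal", "ambiguous")))
  expect_equal(amb$n_total, 1L)
  expect_equal(amb$p_maximal, 1)
  expect_equal(amb$n_ambiguous, 1L)

  expect_error(summarize_classes(data.frame(label = character())), "no classified")
})

test_that("summaries at the EC50 match the binomial oracle", {
  cfg <- tumor_sim_config("mid", true_ec50_mM = 2, true_bottom = 0,
                          true_top = 1, seed = 42)
  s <- simulate_dose_experiment(cfg, 2, traces = FALSE)
  summ <- summarize_classes(data.frame(s$meta, label = s$meta$true_class))
  expect_lt(abs(summ$p_maximal - 0.5), 3 * sqrt(0.25 / 600))
})

test_that("ionophore QC passes fluxing cells and flags flat ones", {
  set.seed(8)
  post_peak <- step_trace(3, 30)
  post_flat <- rep(1, 121) * (1 + rnorm(121, 0, 0.01))
  qc <- ionophore_qc(rep(1, 121), rbind(post_peak, post_flat))
  expect_identical(unname(qc), c(TRUE, FALSE))
  expect_warning(res <- ionophore_qc(rep(1, 121), NULL), "skipped")
  expect_true(is.na(res))

  # planted loading failures are recovered exactly
  set.seed(9)
  n <- 100
  failed <- runif(n) < 0.05
  post <- t(vapply(seq_len(n), function(i) {
    if (failed[i]) 1 + rnorm(121, 0, 0.01)
    else simulate_trace(trace_sim_params("maximal"), seed = i)$raw
  }, numeric(121)))
  expect_identical(sum(!ionophore_qc(NULL, post)), sum(failed))
})
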