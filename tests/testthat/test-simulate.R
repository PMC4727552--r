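test_that("noiseless templates have the stated fixed values", {
  # flat non-responder
  tr <- simulate_trace(trace_sim_params("non_responder", noise_sd = 0), 1)
  expect_length(tr$raw, 121L)
  expect_equal(tr$raw, rep(1, 121))

  # instantaneous-rise maximal: 1.0 before frame 6, 3.0 from frame 6 on
  prm <- trace_sim_params("maximal", amplitude = 2, onset_s = 30,
                          rise_tau_s = 0, noise_sd = 0)
  tr <- simulate_trace(prm, 1)
  expect_equal(tr$raw[1:6], rep(1, 6))
  expect_equal(tr$raw[7:121], rep(3, 115))
})

test_that("trace simulation rejects invalid inputs", {
  expect_error(trace_sim_params("oscillating"), "class_label")
  expect_error(trace_sim_params("maximal", frame_interval_s = 0), "positive")
  expect_error(trace_sim_params("maximal", amplitude = -1), "amplitude")
  expect_error(trace_sim_params("multiple_peak", n_peaks = 1), "n_peaks")
})

test_that("traces are reproducible under a fixed seed and frame 0 is baseline", {
  for (cl in kinetic_classes) {
    p <- trace_sim_params(cl)
    a <- simulate_trace(p, seed = 7)
    b <- simulate_trace(p, seed = 7)
    expect_identical(a$raw, b$raw)
    expect_identical(a$raw[1L], 1)
    c_ <- simulate_trace(p, seed = 8)
    if (cl != "non_responder" || p$noise_sd > 0)
      expect_false(identical(b$raw, c_$raw))
  }
})

test_that("a generated rapid transient satisfies the classifier's own rules", {
  prm <- trace_sim_params("rapid_transient", amplitude = 1.5, onset_s = 20,
                          noise_sd = 0)
  tr <- simulate_trace(prm, 1)
  # template decays to within 10% of baseline well before t = 110 s
  expect_true(all(abs(tr$raw[tr$times_s >= 110] - 1) < 0.10))
  expect_identical(classify_trace(tr)$label, "rapid_transient")
})

test_that("dose experiments follow the generating 4PL mixture", {
  cfg <- tumor_sim_config("T1", true_ec50_mM = 2.4, true_hill = 3,
                          true_bottom = 0.05, true_top = 0.95, seed = 11)
  # at the EC50 the expected maximal fraction is (top + bottom)/2 = 0.5
  s <- simulate_dose_experiment(cfg, 2, traces = FALSE)  # n = 600 labels
  expect_equal(nrow(s$meta), 600L)
  s24 <- simulate_dose_experiment(
    tumor_sim_config("T1", 2.4, dose_series_mM = c(0.5, 1, 2.4, 5, 10),
                     seed = 11), 2.4, traces = FALSE)
  phat <- mean(s24$meta$true_class == "maximal")
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / 600))

  # asymptotes: far below / above the EC50
  lo <- simulate_dose_experiment(
    tumor_sim_config("T2", 100, true_bottom = 0, dose_series_mM = c(0.01, 100),
                     seed = 3), 0.01, traces = FALSE)
  expect_true(all(lo$meta$true_class != "maximal"))
  hi <- simulate_dose_experiment(
    tumor_sim_config("T3", 0.001, true_top = 1, true_bottom = 0.5,
                     dose_series_mM = c(0.001, 500), seed = 4),
    500, traces = FALSE)
  expect_true(all(hi$meta$true_class == "maximal"))

  expect_error(simulate_dose_experiment(cfg, 99), "dose series")
  expect_error(
    simulate_dose_experiment(
      tumor_sim_config("T4", 2.4, residual_class_weights = c(slow = 0),
                       seed = 1), 0.5, traces = FALSE),
    "sum to 0")
})

test_that("maximal fraction converges to the generating 4PL at large n", {
  cfg <- tumor_sim_config("big", true_ec50_mM = 2.4, true_hill = 3,
                          cells_per_field = 5000L, fields_per_dose = 2L,
                          seed = 5)
  for (d in c(1, 2, 5)) {
    s <- simulate_dose_experiment(cfg, d, traces = FALSE)
    p_true <- four_pl(d, 0.05, 0.95, log10(2.4), 3)
    phat <- mean(s$meta$true_class == "maximal")
    expect_lt(abs(phat - p_true),
              3 * sqrt(p_true * (1 - p_true) / 10000))
  }
})

test_that("cohorts are deterministic, reject duplicates, allow empty", {
  cfgs <- list(tumor_sim_config("A", 2.4, cells_per_field = 20L, seed = 1),
               tumor_sim_config("B", 3.6, cells_per_field = 20L, seed = 2))
  c1 <- simulate_cohort(cfgs)
  c2 <- simulate_cohort(cfgs)
  expect_identical(c1, c2)
  expect_named(c1, c("A", "B"))
  expect_error(simulate_cohort(list(cfgs[[1]], cfgs[[1]])), "duplicate")
  expect_identical(simulate_cohort(list()), structure(list(), names = character()))
})

test_that("rendered stacks carry each trace as integrated intensity", {
  geom <- grid_geometry(pixel_size_um = 5, n_rows = 3, n_cols = 3)
  tr <- structure(list(
    meta = data.frame(cell_id = 1L, raft_row = 1L, raft_col = 1L),
    raw = matrix(c(1, 2, 0.5), nrow = 1),
    times_s = c(0, 5, 10)), class = "flux_traces")
  st <- render_stack(tr, geom, background_level = 10, camera_noise_sd = 0,
                     intensity_scale = 10, footprint_px = 2L)
  # trace value 2.0 at frame 2 -> integrated intensity above background 20
  fr <- st$frames[[2L]]
  expect_equal(sum(fr[st$labels == 1L] - 10), 20)
  expect_equal(sum(st$labels > 0), 4L)

  # zero traces -> pure background, extraction warns and yields no regions
  empty <- structure(list(meta = data.frame(cell_id = integer(),
                                            raft_row = integer(),
                                            raft_col = integer()),
                          raw = matrix(numeric(), 0, 3),
                          times_s = c(0, 5, 10)), class = "flux_traces")
  st0 <- render_stack(empty, geom, background_level = 7)
  expect_true(all(vapply(st0$frames, function(f) all(f == 7), logical(1))))
  expect_warning(rec <- integrated_intensity(st0, st0$labels), "empty label")
  expect_identical(nrow(rec$meta), 0L)

  # overlapping footprints rejected
  tr2 <- tr; tr2$meta <- rbind(tr$meta, tr$meta)
  tr2$raw <- rbind(tr$raw, tr$raw)
  expect_error(render_stack(tr2, geom), "same raft")
})

test_that("render -> extract round trip is the identity up to scale", {
  geom <- grid_geometry(pixel_size_um = 2, n_rows = 4, n_cols = 4)
  cfg <- tumor_sim_config("R1", 2.4, cells_per_field = 12L,
                          fields_per_dose = 1L, seed = 9)
  tr <- simulate_dose_experiment(cfg, 2, traces = TRUE, noise_sd = 0)
  st <- render_stack(tr, geom, background_level = 50, camera_noise_sd = 0,
                     intensity_scale = 200, footprint_px = 3L)
  rec <- integrated_intensity(st, st$labels)
  # rows come back in cell_id order; normalized traces match inputs
  ord <- match(rec$meta$cell_id, tr$meta$cell_id)
  got <- rec$raw / rec$raw[, 1L]
  want <- (tr$raw / tr$raw[, 1L])[ord, ]
  expect_lt(max(abs(got - want)), 1e-6)
})
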