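# Volume integration, breath segmentation and phase assignment.

test_that("integrate_volume reproduces analytic integrals", {
  fs <- 200
  t <- seq(0, 1, by = 1 / fs)
  rec <- raw_recording(t, rep(0.1, length(t)), rep(29, length(t)), fs)
  v <- integrate_volume(rec)
  expect_equal(v[length(v)], 100, tolerance = 1e-9)  # 0.1 L/s for 1 s
  # full sine period nets to ~0
  t2 <- seq(0, 2, by = 1 / fs)
  rec2 <- raw_recording(t2, 0.1 * sin(pi * t2), rep(29, length(t2)), fs)
  v2 <- integrate_volume(rec2)
  expect_lt(abs(v2[length(v2)]), 1e-6)
})

test_that("breath count and volumes match the simulated pattern", {
  rec <- cached_sim("exact_small", exact_small_cfg())
  b <- detect_breaths(rec, analysis_config())
  cfg <- attr(rec, "ground_truth")$config
  expect_equal(nrow(b), cfg$n_pre + cfg$n_washin + cfg$n_washout)
  expect_equal(unname(b$vol_insp_ml), rep(30, nrow(b)), tolerance = 0.01)
  expect_equal(unname(b$vol_exp_ml), rep(30, nrow(b)), tolerance = 0.01)
})

test_that("zero flow raises a no-breaths error", {
  t <- seq(0, 5, by = 1 / 200)
  rec <- raw_recording(t, rep(0, length(t)), rep(29, length(t)), 200)
  expect_error(detect_breaths(rec, analysis_config()),
               class = "mbw_no_breaths")
  short <- raw_recording(t[1:100], rep(0.1, 100), rep(29, 100), 200)
  expect_error(detect_breaths(short, analysis_config()),
               class = "mbw_no_breaths")
})

test_that("flow noise of 5% amplitude does not change the breath count", {
  rec <- cached_sim("exact_small", exact_small_cfg())
  n0 <- nrow(detect_breaths(rec, analysis_config()))
  amp <- max(rec$flow)
  set.seed(99)
  noisy <- raw_recording(rec$time, rec$flow + rnorm(length(rec$flow),
                                                    0, 0.05 * amp),
                         rec$molar_mass, rec$sampling_rate, rec$meta)
  expect_equal(nrow(detect_breaths(noisy, analysis_config())), n0)
})

test_that("segmentation is invariant under uniform flow rescaling", {
  rec <- cached_sim("noisy_small", noisy_small_cfg())
  b1 <- detect_breaths(rec, analysis_config())
  scaled <- raw_recording(rec$time, 2.5 * rec$flow, rec$molar_mass,
                          rec$sampling_rate, rec$meta)
  b2 <- detect_breaths(scaled, analysis_config())
  expect_equal(b2$i_insp, b1$i_insp)
  expect_equal(b2$i_end, b1$i_end)
  expect_equal(b2$vol_exp_ml, 2.5 * b1$vol_exp_ml, tolerance = 1e-9)
})

test_that("phase boundaries are recovered exactly on simulated data", {
  for (key in c("exact_small", "noisy_small")) {
    rec <- cached_sim(key, if (key == "exact_small") exact_small_cfg()
                      else noisy_small_cfg())
    b <- detect_breaths(rec, analysis_config())
    ph <- detect_phases(rec, b, analysis_config())
    gt <- attr(rec, "ground_truth")
    expect_equal(ph$washin[1], gt$washin_range[1])
    expect_equal(ph$washout[1], gt$washout_range[1])
    expect_true(ph$washin_complete)
    # contiguous ordered ranges
    expect_equal(ph$pre[2] + 1L, ph$washin[1])
    expect_equal(ph$washin[2] + 1L, ph$washout[1])
  }
})

test_that("a recording truncated before washout raises missing-washout", {
  rec <- cached_sim("no_washout",
                    simulation_config(n_washout = 0, seed = 5))
  b <- detect_breaths(rec, analysis_config())
  expect_error(detect_phases(rec, b, analysis_config()),
               class = "mbw_missing_washout")
})

test_that("washin stopped near 60% equilibration clears the complete flag", {
  # 4 washin breaths at FRC 80 / VT 30 reach ~65% of the plateau
  rec <- cached_sim("short_washin",
                    simulation_config(frc_ml = 80, vt_ml = 30, rr_bpm = 30,
                                      n_washin = 4, seed = 5))
  b <- detect_breaths(rec, analysis_config())
  ph <- detect_phases(rec, b, analysis_config())
  expect_false(ph$washin_complete)
  expect_error(analyze_recording(rec, atp_config(), strict = TRUE),
               class = "mbw_washin_incomplete")
})

test_that("tracer-free recordings raise missing-washin", {
  t <- seq(0, 30, by = 1 / 200)
  flow <- 0.05 * sin(2 * pi * t)
  rec <- raw_recording(t, flow, rep(29, length(t)) , 200)
  b <- detect_breaths(rec, analysis_config())
  expect_error(detect_phases(rec, b, analysis_config()),
               class = "mbw_missing_washin")
})
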