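# BTPS flow correction, end-of-test rule, FRC/CEV/LCI computation.

test_that("BTPS correction: identity conditions leave flow unchanged", {
  rec <- cached_sim("exact_small", exact_small_cfg())
  b <- detect_breaths(rec, analysis_config())
  body <- ambient_conditions(temperature = 310.15, relative_humidity = 1)
  expect_equal(btps_correct_flow(rec, b, body, "btps"), rec$flow,
               tolerance = 1e-12)
  expect_equal(btps_correct_flow(rec, b, mode = "none"), rec$flow)
})

test_that("BTPS factors are applied phase-wise", {
  rec <- cached_sim("exact_small", exact_small_cfg())
  b <- detect_breaths(rec, analysis_config())
  cond <- ambient_conditions(temperature = 295.15, relative_humidity = 0.5)
  out <- btps_correct_flow(rec, b, cond, "btps")
  f_in <- btps_factor(cond, "inspiration")
  f_ex <- btps_factor(cond, "expiration")
  ii <- b$i_insp[2]:(b$i_exp[2] - 1)
  ie <- b$i_exp[2]:b$i_end[2]
  expect_equal(out[ii], rec$flow[ii] * f_in, tolerance = 1e-12)
  expect_equal(out[ie], rec$flow[ie] * f_ex, tolerance = 1e-12)
})

test_that("end-of-test rule reproduces the threshold example", {
  # threshold 0.025 * 4% = 0.1%; first end-tidal below it is breath 5
  et <- c(4, 2, 1, 0.2, 0.09) / 100
  expect_equal(detect_end_of_test(et, ratio = 0.025), 5)
  expect_error(detect_end_of_test(c(4, 2, 1) / 100, ratio = 0.025),
               class = "mbw_washout_incomplete")
})

test_that("consensus mode requires three consecutive breaths below threshold", {
  et <- c(4, 0.09, 0.2, 0.09, 0.08, 0.07) / 100
  expect_equal(detect_end_of_test(et, 0.025), 2)
  expect_equal(detect_end_of_test(et, 0.025, consensus = TRUE), 4)
})

test_that("end-of-test matches the geometric-dilution closed form", {
  for (key in c("exact_small", "exact_large")) {
    cfg <- if (key == "exact_small") exact_small_cfg() else
      simulation_config(frc_ml = 210, vt_ml = 50, rr_bpm = 20,
                        dead_space_ml = 9.6, chamber_fraction = 0,
                        noise_sd_gmol = 0, tidal_temp_amp_k = 0,
                        humidity_tidal = FALSE, seed = 7)
    rec <- cached_sim(key, cfg)
    res <- analyze_recording(rec, atp_config(cfg$dead_space_ml))
    r <- dilution_ratio(sum(cfg$frc_ml), cfg$vt_ml, cfg$dead_space_ml)
    expect_equal(res$outcomes$eot_breath, ceiling(log(0.025) / log(r)))
  }
})

test_that("noiseless single-compartment FRC is recovered within 1%", {
  rec <- cached_sim("exact_small", exact_small_cfg())
  res <- analyze_recording(rec, atp_config())
  expect_equal(res$outcomes$frc_ml, 80, tolerance = 0.01 * 80)
})

test_that("dead-space setting shifts FRC by exactly its value", {
  rec <- cached_sim("exact_small", exact_small_cfg())
  f1 <- analyze_recording(rec, atp_config(dead_space_ml = 0))$outcomes$frc_ml
  f2 <- analyze_recording(rec, atp_config(dead_space_ml = 4.6))$outcomes$frc_ml
  expect_equal(f1 - f2, 4.6, tolerance = 1e-9)
})

test_that("FRC is invariant under doubling flow and halving time", {
  rec <- cached_sim("exact_small", exact_small_cfg())
  res1 <- analyze_recording(rec, atp_config())
  rec2 <- raw_recording(rec$time / 2, rec$flow * 2, rec$molar_mass,
                        rec$sampling_rate * 2, rec$meta)
  res2 <- analyze_recording(rec2, atp_config())
  expect_equal(res2$outcomes$frc_ml, res1$outcomes$frc_ml,
               tolerance = 0.002 * res1$outcomes$frc_ml)
})

test_that("LCI equals CEV/FRC and follows the single-compartment oracle", {
  rec <- cached_sim("exact_small", exact_small_cfg())
  res <- analyze_recording(rec, atp_config())
  o <- res$outcomes
  expect_equal(o$lci_to, o$cev_ml / o$frc_ml, tolerance = 1e-9)
  r <- dilution_ratio(80, 30, 4.6)
  n <- ceiling(log(0.025) / log(r))
  # LCI ~ n effective expired volumes per FRC, within one breath-equivalent
  expect_equal(o$lci_to, n * (30 - 4.6) / 80,
               tolerance = (30 - 4.6) / 80)
})

test_that("ventilation asymmetry raises LCI against the matched single compartment", {
  cfg2 <- simulation_config(frc_ml = c(40, 40), vent_frac = c(0.7, 0.3),
                            vt_ml = 30, rr_bpm = 30, dead_space_ml = 4.6,
                            chamber_fraction = 0, noise_sd_gmol = 0,
                            tidal_temp_amp_k = 0, humidity_tidal = FALSE,
                            n_washout = 60, seed = 7)
  rec2 <- cached_sim("exact_vi", cfg2)
  lci2 <- analyze_recording(rec2, atp_config())$outcomes$lci_to
  rec1 <- cached_sim("exact_small", exact_small_cfg())
  lci1 <- analyze_recording(rec1, atp_config())$outcomes$lci_to
  expect_gt(lci2, lci1)
})
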