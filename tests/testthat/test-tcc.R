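# Boundary respirograms and the tidal change correction.

analyzed_parts <- function(rec, cfg = analysis_config()) {
  b <- detect_breaths(rec, cfg)
  ph <- detect_phases(rec, b, cfg)
  rg <- build_respirograms(rec, b, ph, cfg)
  list(b = b, ph = ph, rg = rg,
       norm = apply_tcc(rec, b, ph, rg, cfg))
}

test_that("respirograms of identical noiseless breaths equal a single breath", {
  rec <- cached_sim("exact_small", exact_small_cfg())
  p <- analyzed_parts(rec)
  ann <- p$norm
  # compare the pre-phase expirogram against one pre-phase breath's samples
  rg <- p$rg$min_exp
  one <- ann[ann$breath == 2 & ann$phase == "exp", ]
  mm_interp <- approx(one$v_ml, rec$molar_mass[one$index],
                      xout = rg$volume, rule = 2)$y
  expect_equal(rg$mm, mm_interp, tolerance = 0.02)
})

test_that("max-SF6 expirogram lies strictly above the min-SF6 expirogram", {
  rec <- cached_sim("noisy_small", noisy_small_cfg())
  p <- analyzed_parts(rec)
  shared <- intersect(p$rg$min_exp$volume, p$rg$max_exp$volume)
  lo <- p$rg$min_exp$mm[match(shared, p$rg$min_exp$volume)]
  hi <- p$rg$max_exp$mm[match(shared, p$rg$max_exp$volume)]
  expect_true(all(hi > lo))
})

test_that("per-bin median is robust to one corrupted contributing breath", {
  # five values per bin; replacing one with an outlier leaves the median
  # within the range spanned by the other four
  vals <- c(29.1, 29.2, 29.15, 29.18, 29.12)
  expect_equal(median(vals), median(c(vals[-5], 45)), tolerance = 0.06)
  expect_equal(median(c(vals[-5], 45)), 29.18)
})

test_that("samples on the boundary traces normalise to 0, 1 and 0.5", {
  rec <- cached_sim("exact_small", exact_small_cfg())
  cfg <- analysis_config()
  b <- detect_breaths(rec, cfg)
  ph <- detect_phases(rec, b, cfg)
  rg <- build_respirograms(rec, b, ph, cfg)
  # all breaths are identical in shape, so replacing a washout breath's
  # molar mass with a boundary breath's trace puts it exactly on that trace
  wash_b <- ph$washout[1] + 2
  pre_b <- 2
  max_b <- ph$washin[2] - 1
  idx_w <- b$i_insp[wash_b]:b$i_end[wash_b]
  idx_p <- b$i_insp[pre_b]:b$i_end[pre_b]
  idx_m <- b$i_insp[max_b]:b$i_end[max_b]
  n <- min(length(idx_w), length(idx_p), length(idx_m))
  variants <- list(on_min = rec$molar_mass[idx_p][1:n],
                   on_max = rec$molar_mass[idx_m][1:n])
  variants$midpoint <- (variants$on_min + variants$on_max) / 2
  targets <- c(on_min = 0, on_max = 1, midpoint = 0.5)
  for (vn in names(variants)) {
    mm2 <- rec$molar_mass
    mm2[idx_w[1:n]] <- variants[[vn]]
    rec2 <- raw_recording(rec$time, rec$flow, mm2, rec$sampling_rate,
                          rec$meta)
    norm2 <- apply_tcc(rec2, b, ph, rg, cfg)
    x_w <- norm2$x[norm2$breath == wash_b]
    expect_equal(median(x_w, na.rm = TRUE), unname(targets[vn]),
                 tolerance = 0.02)
  }
})

test_that("tidal confounders cancel: pre-phase ~0, washin plateau ~1", {
  rec <- cached_sim("confounded",
                    simulation_config(frc_ml = 80, vt_ml = 30, rr_bpm = 30,
                                      chamber_fraction = 0,
                                      tidal_temp_amp_k = 2,
                                      humidity_tidal = TRUE, seed = 5))
  p <- analyzed_parts(rec)
  pre <- p$norm$breath <= p$ph$pre[2]
  plateau <- p$norm$breath >= p$ph$washin[2] - 2 &
    p$norm$breath <= p$ph$washin[2]
  expect_lt(mean(abs(p$norm$x[pre])), 0.02)
  expect_lt(mean(abs(p$norm$x[plateau] - 1)), 0.02)
})

test_that("insufficient boundary breaths raise a typed error", {
  rec <- cached_sim("exact_small", exact_small_cfg())
  cfg <- analysis_config()
  b <- detect_breaths(rec, cfg)
  ph <- detect_phases(rec, b, cfg)
  ph$pre <- c(1L, 2L)   # pretend only two pre-phase breaths
  expect_error(build_respirograms(rec, b, ph, cfg),
               class = "mbw_insufficient_boundary")
})

test_that("indistinct boundary traces are rejected", {
  # a recording whose 'washin' rise is large enough to be detected but the
  # respirograms are artificially collapsed via a near-zero tracer span
  rec <- cached_sim("exact_small", exact_small_cfg())
  cfg <- analysis_config()
  b <- detect_breaths(rec, cfg)
  ph <- detect_phases(rec, b, cfg)
  rg <- build_respirograms(rec, b, ph, cfg)
  rg_bad <- rg
  rg_bad$max_exp$mm <- rg_bad$min_exp$mm + 0.01
  rg_bad$max_insp$mm <- rg_bad$min_insp$mm + 0.01
  expect_error(apply_tcc(rec, b, ph, rg_bad, cfg),
               class = "mbw_boundary_indistinct")
})
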