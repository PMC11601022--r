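# Side-chamber correction: carry-over fits, minimum-curve interpolation,
# maximum-curve scaling and SF6 extraction.

test_that("exponential fitter recovers known parameters within 5%", {
  set.seed(42)
  v <- seq(1, 30, length.out = 150)
  x <- 0.3 * exp(-v / 15) + rnorm(length(v), 0, 0.003)  # ~1% of a
  fit <- sf6mbw:::fit_exp_decay(v, x)
  expect_equal(fit$method, "exponential")
  expect_equal(fit$a, 0.3, tolerance = 0.05)
  expect_equal(fit$lambda, 15, tolerance = 0.05 * 15)
  # model form tends to 0 at large volume
  expect_lt(fit$fun(1e4), 1e-9)
})

test_that("a flat zero inspiration yields a = 0", {
  set.seed(1)
  v <- seq(1, 30, length.out = 150)
  x <- rnorm(length(v), 0, 0.004)
  fit <- sf6mbw:::fit_exp_decay(v, x)
  expect_equal(fit$a, 0)
  expect_equal(fit$fun(c(0, 10, 30)), c(0, 0, 0))
})

make_synthetic_washout <- function(a_vals, lambda = 15, vt = 30,
                                   n_per_phase = 60) {
  # two-breath washout skeleton with prescribed carry-over per inspiration
  rows <- list()
  tt <- 0
  for (k in seq_along(a_vals)) {
    v <- seq(0.25, vt, length.out = n_per_phase)
    t_i <- tt + seq_len(n_per_phase) / n_per_phase
    t_e <- t_i[n_per_phase] + seq_len(n_per_phase) / n_per_phase
    rows[[2 * k - 1]] <- data.frame(breath = k, phase = "insp", v_ml = v,
                                    time = t_i,
                                    x = a_vals[k] * exp(-v / lambda))
    rows[[2 * k]] <- data.frame(breath = k, phase = "exp", v_ml = v,
                                time = t_e, x = 0.5)
    tt <- t_e[n_per_phase]
  }
  norm <- do.call(rbind, rows)
  norm$index <- seq_len(nrow(norm))
  norm$over_range <- FALSE
  class(norm) <- c("normalized_signal", "data.frame")
  phases <- structure(list(pre = c(1L, 0L), washin = c(1L, 0L),
                           washout = c(1L, length(a_vals)),
                           washin_complete = TRUE),
                      class = "phase_annotation")
  list(norm = norm, phases = phases)
}

test_that("minimum curve interpolates continuously between flanking fits", {
  # choose the second carry-over equal to the first fit's end value, so the
  # flanking values of the first expiration coincide -> constant interpolant
  a1 <- 0.3
  a2 <- a1 * exp(-30 / 15)
  s <- make_synthetic_washout(c(a1, a2, a2 * exp(-30 / 15)))
  fits <- fit_inspiration_minimum(s$norm, NULL, s$phases)
  m <- interpolate_minimum_curve(fits, s$norm, s$phases)
  w <- s$norm
  e1 <- which(w$breath == 1 & w$phase == "exp")
  expect_equal(m[e1], rep(fits[[1]]$end_val, length(e1)),
               tolerance = 0.02 * fits[[1]]$end_val)
  # continuity: the expiration interpolant ends exactly at the next fit's
  # start value
  for (k in 1:2) {
    last_exp <- max(which(w$breath == k & w$phase == "exp"))
    expect_equal(m[last_exp], fits[[k + 1]]$a,
                 tolerance = 1e-6 + 0.02 * fits[[k + 1]]$a)
  }
})

test_that("minimum curve tracks the true chamber state on full simulation", {
  rec <- cached_sim("noisy_small", noisy_small_cfg())
  res <- analyze_recording(rec, atp_config())
  corr <- attr(res$sf6, "correction")
  gt <- attr(rec, "ground_truth")
  wsel <- res$normalized$breath >= res$phases$washout[1]
  truth <- 0.1 * gt$chamber_state[res$normalized$index[wsel]] / 0.04
  rms <- sqrt(mean((corr$min_curve - truth)^2))
  expect_lt(rms, 0.15 * diff(range(truth)))
})

test_that("scaling recovers the no-chamber limit and the chamber fraction", {
  # chamber-free: alpha ~ 1, beta ~ 1, so extraction reduces to C_max * x
  rec0 <- cached_sim("exact_small", exact_small_cfg())
  res0 <- analyze_recording(rec0, atp_config())
  sc0 <- attr(res0$sf6, "correction")$scaling
  expect_equal(sc0$alpha, 1, tolerance = 0.02)
  expect_equal(sc0$beta, 1, tolerance = 0.02)
  # chambered, noiseless: alpha ~ 1 - w, beta ~ 1
  rec1 <- cached_sim("exact_chamber", exact_small_cfg(chamber_fraction = 0.1,
                                                      chamber_lambda_ml = 15))
  res1 <- analyze_recording(rec1, atp_config())
  sc1 <- attr(res1$sf6, "correction")$scaling
  expect_equal(sc1$alpha, 0.9, tolerance = 0.01)
  expect_equal(sc1$beta, 1, tolerance = 0.02)
})

test_that("extraction returns 0 on the minimum curve and C_max on the maximum", {
  s <- make_synthetic_washout(c(0.3, 0.25))
  fits <- fit_inspiration_minimum(s$norm, NULL, s$phases)
  m <- interpolate_minimum_curve(fits, s$norm, s$phases)
  scaling <- structure(list(alpha = 0.7, beta = 1, m0 = 0.3,
                            chamber_fraction_hat = 0.3),
                       class = "side_chamber_scaling")
  # put the washout samples exactly on the min curve -> 0 everywhere
  s0 <- s
  s0$norm$x <- m
  # a washin breath is needed for the plateau extraction; fake one
  s0$phases$washin <- c(1L, 1L)
  s0$phases$washout <- c(2L, 2L)
  m2 <- m[s0$norm$breath >= 2]
  out0 <- extract_sf6(s0$norm, m2, scaling, NULL, s0$phases, c_max = 0.04)
  expect_equal(max(abs(out0$sf6)), 0, tolerance = 1e-12)
  # on the max curve -> C_max
  s1 <- s0
  s1$norm$x <- scaling$alpha + scaling$beta * m
  out1 <- extract_sf6(s1$norm, m2, scaling, NULL, s1$phases, c_max = 0.04)
  expect_equal(unname(range(out1$sf6)), c(0.04, 0.04), tolerance = 1e-9)
})

test_that("extracted end-tidal series matches simulated truth within 2% of C_max", {
  rec <- cached_sim("noisy_small", noisy_small_cfg())
  res <- analyze_recording(rec, atp_config())
  gt <- attr(rec, "ground_truth")
  truth <- gt$breath$c_mix[gt$breath$phase == "washout"]
  est <- res$sf6$et$et_sf6
  expect_lt(max(abs(est - truth[seq_along(est)])), 0.02 * 0.04)
})

test_that("end-tidal series decays monotonically after median smoothing", {
  rec <- cached_sim("exact_chamber", exact_small_cfg(chamber_fraction = 0.1))
  res <- analyze_recording(rec, atp_config())
  et <- stats::runmed(res$sf6$et$et_sf6, 3)
  expect_true(all(diff(et) <= 1e-7))
})

test_that("correction reduces FRC error iff a chamber is present", {
  frc_of <- function(chf, corr_on) {
    key <- sprintf("abl_%g", chf)
    rec <- cached_sim(key, noisy_small_cfg(chamber_fraction = chf))
    analyze_recording(rec, atp_config(side_chamber_correction = corr_on)
                      )$outcomes$frc_ml
  }
  err <- function(f) abs(f - 80) / 80
  expect_lt(err(frc_of(0.1, TRUE)), err(frc_of(0.1, FALSE)))
  expect_lt(abs(frc_of(0, TRUE) - frc_of(0, FALSE)) / frc_of(0, FALSE), 0.005)
})
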