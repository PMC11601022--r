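# Physics-based forward simulator of tracer washin/washout recordings.
#
# The gas side is a parallel-compartment lung model with perfect per-breath
# mixing, shared apparatus dead space and sinusoidal flow. The measurement
# side reproduces how an ultrasonic flowmeter actually produces its signal:
# the local speed of sound follows from the instantaneous gas composition,
# humidity and temperature, and a "device" inverts it assuming a fixed
# calibration temperature and adiabatic index — which is what creates the
# tidal confounders the analysis has to remove. A lumped first-order side
# chamber (volume constant in mL of through-flow) contaminates the displayed
# molar mass, and Gaussian sensor noise is added last.

#' Simulation configuration
#'
#' @param frc_ml Compartment gas volumes in mL (vector; one element per
#'   compartment). Total FRC is their sum.
#' @param vent_frac Fraction of the tidal volume ventilating each compartment;
#'   must sum to 1.
#' @param vt_ml Tidal volume, mL.
#' @param rr_bpm Respiratory rate, breaths/min.
#' @param dead_space_ml Apparatus dead space between sensor and lung, mL.
#' @param tracer_fraction Supply SF6 mole fraction during washin.
#' @param n_pre,n_washin,n_washout Breath counts of the three phases.
#' @param chamber_fraction Side-chamber share of the measurement path (0 = no
#'   chamber).
#' @param chamber_lambda_ml Side-chamber volume constant, mL of through-flow.
#' @param temp_sensor_k Sensor/calibration temperature, K.
#' @param tidal_temp_amp_k Tidal temperature amplitude at the sensor, K
#'   (expired gas asymptotes `temp_sensor_k + tidal_temp_amp_k`).
#' @param temp_volume_constant_ml Volume constant (mL) of the within-breath
#'   temperature/humidity transition.
#' @param rh_ambient Ambient (inspired-gas) relative humidity.
#' @param humidity_tidal Enable tidal humidity swings (expired gas saturates).
#' @param pressure_pa Ambient pressure, Pa.
#' @param co2_exchange Enable steady O2/CO2 exchange (5% CO2 in alveolar gas,
#'   O2 reduced accordingly); off for the water-bath lung model.
#' @param noise_sd_gmol SD of additive Gaussian sensor noise on the displayed
#'   molar mass, g/mol.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param dead_space_transition_ml Width (mL) of the smooth dead-space /
#'   alveolar gas front at the sensor during expirations.
#' @param seed Integer seed fixing the full sample path.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(frc_ml = 80, vent_frac = 1, vt_ml = 30,
                              rr_bpm = 30, dead_space_ml = 4.6,
                              tracer_fraction = 0.04,
                              n_pre = 10, n_washin = 30, n_washout = 45,
                              chamber_fraction = 0.10,
                              chamber_lambda_ml = 15,
                              temp_sensor_k = 296.15,
                              tidal_temp_amp_k = 2.85,
                              temp_volume_constant_ml = 8,
                              rh_ambient = 0.3,
                              humidity_tidal = TRUE,
                              pressure_pa = 101325,
                              co2_exchange = FALSE,
                              noise_sd_gmol = 0.02,
                              sampling_rate_hz = 200,
                              dead_space_transition_ml = 0.7,
                              seed = 1L) {
  if (length(frc_ml) != length(vent_frac))
    stop_mbw("frc_ml and vent_frac must have the same length",
             "mbw_invalid_config")
  if (abs(sum(vent_frac) - 1) > 1e-9)
    stop_mbw("ventilation fractions must sum to 1", "mbw_invalid_config")
  if (any(frc_ml <= 0) || vt_ml <= 0 || rr_bpm <= 0)
    stop_mbw("volumes and rates must be positive", "mbw_invalid_config")
  if (dead_space_ml >= vt_ml)
    stop_mbw("dead space must be smaller than the tidal volume",
             "mbw_invalid_config")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a washin/washout recording
#'
#' Forward-models the full measurement chain (see the package vignette) and
#' returns a `raw_recording` whose `ground_truth` attribute carries the exact
#' simulated state: total FRC, per-breath compartment and mixed-expirate
#' concentrations, the sensed (noise- and chamber-free) SF6 fraction per
#' sample, the side-chamber tracer state, and exact per-breath tracer
#' bookkeeping for conservation checks.
#'
#' @param cfg A [simulation_config()].
#' @return A `raw_recording` with attribute `ground_truth`.
#' @export
simulate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  fs <- cfg$sampling_rate_hz
  dt <- 1 / fs
  t_half <- 30 / cfg$rr_bpm
  n_half <- max(4L, round(t_half * fs))
  tau <- (seq_len(n_half) - 0.5) * dt
  amp_flow <- pi * cfg$vt_ml / (2000 * t_half)          # L/s
  flow_half <- amp_flow * sin(pi * tau / t_half)
  v_half <- (cfg$vt_ml / 2) * (1 - cos(pi * tau / t_half))  # mL within phase

  nb <- cfg$n_pre + cfg$n_washin + cfg$n_washout
  phase_of <- rep(c("pre", "washin", "washout"),
                  c(cfg$n_pre, cfg$n_washin, cfg$n_washout))
  nc <- length(cfg$frc_ml)
  conc <- rep(0, nc)                 # compartment SF6 fractions
  c_ds <- 0                          # dead-space (lung-side) content
  vd <- cfg$dead_space_ml
  vt <- cfg$vt_ml
  f <- cfg$vent_frac

  air <- unclass(dry_air())
  sf6_pure <- c(n2 = 0, o2 = 0, co2 = 0, ar = 0, sf6 = 1, h2o = 0)
  v_tc <- cfg$temp_volume_constant_ml
  t_amp <- cfg$tidal_temp_amp_k
  t_base <- cfg$temp_sensor_k
  gamma_dev <- 1.400

  # temperature / humidity profiles, functions of volume within phase
  temp_insp <- t_base + t_amp * exp(-v_half / v_tc)
  temp_exp <- t_base + t_amp * (1 - exp(-v_half / v_tc))
  if (cfg$humidity_tidal) {
    rh_insp <- cfg$rh_ambient + (1 - cfg$rh_ambient) * exp(-v_half / v_tc)
    rh_exp <- 1 - (1 - cfg$rh_ambient) * exp(-v_half / v_tc)
  } else {
    rh_insp <- rh_exp <- rep(cfg$rh_ambient, n_half)
  }
  w_alv <- stats::plogis((v_half - vd) / cfg$dead_space_transition_ml)

  displayed_mm <- function(c_sf6, temp, rh, alveolar_mix) {
    # dry composition: air diluted by SF6 (and optional alveolar CO2/O2 shift)
    comp <- outer(1 - c_sf6, air) + outer(c_sf6, sf6_pure)
    if (cfg$co2_exchange) {
      shift <- 0.05 * alveolar_mix
      comp[, "co2"] <- comp[, "co2"] + shift
      comp[, "o2"] <- comp[, "o2"] - shift
    }
    xh <- rh * saturation_vapor_pressure(temp) / cfg$pressure_pa
    comp <- comp * (1 - xh)
    comp[, "h2o"] <- comp[, "h2o"] + xh
    mm <- .mm_matrix(comp)
    gam <- .gamma_matrix(comp)
    # device inversion at fixed calibration temperature and adiabatic index
    mm * (gamma_dev * t_base) / (gam * temp)
  }

  mm_disp <- numeric(0)
  flow <- numeric(0)
  c_dry <- numeric(0)
  comp_hist <- matrix(NA_real_, nb, nc)
  cmix_hist <- numeric(nb)
  book_in <- numeric(nb)
  book_out <- numeric(nb)
  content_hist <- numeric(nb)

  for (b in seq_len(nb)) {
    supply <- if (phase_of[b] == "washin") cfg$tracer_fraction else 0
    # compartment update: dead-space re-breathing plus fresh supply
    conc <- (conc * cfg$frc_ml + f * vd * c_ds + f * (vt - vd) * supply) /
      (cfg$frc_ml + f * vt)
    c_mix <- sum(f * conc)
    book_in[b] <- supply * vt
    book_out[b] <- supply * vd + c_mix * (vt - vd)
    comp_hist[b, ] <- conc
    cmix_hist[b] <- c_mix
    # inspiration: sensor sees supply gas
    c_in <- rep(supply, n_half)
    mm_in <- displayed_mm(c_in, temp_insp, rh_insp, alveolar_mix = 0)
    # expiration: dead-space front, then mixed alveolar gas
    c_ex <- (1 - w_alv) * supply + w_alv * c_mix
    mm_ex <- displayed_mm(c_ex, temp_exp, rh_exp, alveolar_mix = w_alv)
    mm_disp <- c(mm_disp, mm_in, mm_ex)
    flow <- c(flow, flow_half, -flow_half)
    c_dry <- c(c_dry, c_in, c_ex)
    c_ds <- c_mix
    content_hist[b] <- sum(conc * cfg$frc_ml) + vd * c_ds
  }

  n <- length(mm_disp)
  time <- (seq_len(n) - 1) * dt

  # lumped first-order side chamber on the displayed molar mass
  w <- cfg$chamber_fraction
  s_ch <- rep(NA_real_, n)
  if (w > 0) {
    dv <- abs(flow) * dt * 1000
    e <- exp(-dv / cfg$chamber_lambda_ml)
    mm_ch <- numeric(n)
    ch_c <- numeric(n)     # chamber tracer state (ground truth)
    mm_prev <- mm_disp[1]
    c_prev <- 0
    for (k in seq_len(n)) {
      mm_prev <- mm_disp[k] + (mm_prev - mm_disp[k]) * e[k]
      c_prev <- c_dry[k] + (c_prev - c_dry[k]) * e[k]
      mm_ch[k] <- mm_prev
      ch_c[k] <- c_prev
    }
    mm_meas <- (1 - w) * mm_disp + w * mm_ch
    s_ch <- ch_c
  } else {
    mm_meas <- mm_disp
  }
  if (cfg$noise_sd_gmol > 0)
    mm_meas <- mm_meas + stats::rnorm(n, 0, cfg$noise_sd_gmol)

  amb <- ambient_conditions(temperature = cfg$temp_sensor_k,
                            pressure = cfg$pressure_pa,
                            relative_humidity = cfg$rh_ambient,
                            body_temperature = min(320, max(270,
                              cfg$temp_sensor_k + cfg$tidal_temp_amp_k)))
  rec <- raw_recording(time, flow, mm_meas, sampling_rate = fs,
                       meta = list(ambient = amb,
                                   dead_space_ml = cfg$dead_space_ml,
                                   tracer_fraction = cfg$tracer_fraction,
                                   frc_true_ml = sum(cfg$frc_ml)))
  attr(rec, "ground_truth") <- list(
    frc_true_ml = sum(cfg$frc_ml),
    breath = data.frame(breath = seq_len(nb), phase = phase_of,
                        c_mix = cmix_hist, content = content_hist,
                        book_in = book_in, book_out = book_out),
    compartments = comp_hist,
    c_dry = c_dry,
    chamber_state = s_ch,
    washin_range = c(cfg$n_pre + 1L, cfg$n_pre + cfg$n_washin),
    washout_range = c(cfg$n_pre + cfg$n_washin + 1L, nb),
    config = cfg)
  rec
}

#' In-vitro condition grid
#'
#' Builds the two-volume by five-condition grid of the lung-model validation
#' experiment: small (FRC 80 mL, VT 30 mL, RR 30/min) and large (FRC 210 mL,
#' VT 50 mL, RR 20/min) baselines at a 32.5 C water bath, with variants
#' measured at room temperature (-T), at increased respiratory rate (+RR:
#' small 50/min, large 30/min), at increased tidal volume (+VT: small 50 mL,
#' large 80 mL), and with a ventilation-inhomogeneity insert (+VI: two equal
#' compartments with a 0.7/0.3 ventilation split). Each of the 10 cells is
#' replicated with `replicates` distinct seeds.
#'
#' @param replicates Seeded replicates per cell (default 6, giving 60 runs).
#' @param seed Base seed; replicate seeds are derived from it.
#' @return A data frame with columns `size`, `condition`, `rep`, `seed` and a
#'   list-column `config` of [simulation_config()] objects.
#' @export
condition_grid <- function(replicates = 6, seed = 1) {
  sizes <- list(
    small = list(frc = 80, vt = 30, rr = 30, vd = 4.6,
                 rr_hi = 50, vt_hi = 50),
    large = list(frc = 210, vt = 50, rr = 20, vd = 9.6,
                 rr_hi = 30, vt_hi = 80)
  )
  conditions <- c("standard", "-T", "+RR", "+VT", "+VI")
  t_sensor <- 296.15
  bath_standard <- 305.65    # 32.5 C water bath
  bath_room <- 293.15        # room temperature
  rows <- list()
  cell <- 0L
  for (sz in names(sizes)) {
    p <- sizes[[sz]]
    for (cond in conditions) {
      cell <- cell + 1L
      bath <- if (cond == "-T") bath_room else bath_standard
      vt <- if (cond == "+VT") p$vt_hi else p$vt
      rr <- if (cond == "+RR") p$rr_hi else p$rr
      if (cond == "+VI") {
        frc <- rep(p$frc / 2, 2); vf <- c(0.7, 0.3)
      } else {
        frc <- p$frc; vf <- 1
      }
      # partial thermal equilibration between lung model and sensor
      t_amp <- 0.3 * (bath - t_sensor)
      for (r in seq_len(replicates)) {
        sd_r <- (as.integer(seed) * 10000L + cell * 100L + r) %%
          .Machine$integer.max
        rows[[length(rows) + 1L]] <- list(
          size = sz, condition = cond, rep = r, seed = sd_r,
          config = simulation_config(
            frc_ml = frc, vent_frac = vf, vt_ml = vt, rr_bpm = rr,
            dead_space_ml = p$vd, temp_sensor_k = t_sensor,
            tidal_temp_amp_k = t_amp, seed = sd_r))
      }
    }
  }
  out <- data.frame(
    size = vapply(rows, `[[`, character(1), "size"),
    condition = vapply(rows, `[[`, character(1), "condition"),
    rep = vapply(rows, `[[`, integer(1), "rep"),
    seed = vapply(rows, `[[`, numeric(1), "seed"))
  out$config <- lapply(rows, `[[`, "config")
  out
}

#' Ventilation-asymmetry sweep configurations
#'
#' Two equal-volume compartments at fixed total FRC and VT, with the
#' ventilation split swept from symmetric (0.5/0.5) outward. Because the end
#' of test is a whole-breath index, LCI changes in quanta of one breath; the
#' default sweep points are spaced so consecutive points differ by at least
#' one end-of-test breath under the closed-form dilution model.
#'
#' @param asymmetry Offsets of the ventilation fraction from 0.5.
#' @param frc_ml Total FRC (split equally), mL.
#' @param vt_ml Tidal volume, mL.
#' @param rr_bpm Respiratory rate, breaths/min.
#' @param ... Further arguments passed to [simulation_config()].
#' @return A list of [simulation_config()] objects, one per sweep point.
#' @export
asymmetry_sweep <- function(asymmetry = c(0, 0.2, 0.3, 0.35, 0.4),
                            frc_ml = 80, vt_ml = 30, rr_bpm = 30, ...) {
  lapply(asymmetry, function(a) {
    simulation_config(frc_ml = rep(frc_ml / 2, 2),
                      vent_frac = c(0.5 + a, 0.5 - a),
                      vt_ml = vt_ml, rr_bpm = rr_bpm,
                      n_washout = 90,
                      chamber_fraction = 0, noise_sd_gmol = 0,
                      tidal_temp_amp_k = 0, humidity_tidal = FALSE, ...)
  })
}

#' Run the condition grid and collect FRC errors
#'
#' Simulates every run of [condition_grid()], analyzes each recording with the
#' full pipeline (ATP volume reporting, dead space matched to the apparatus),
#' and returns per-run FRC errors.
#'
#' @param grid A grid from [condition_grid()]; built with defaults if omitted.
#' @param replicates,seed Passed to [condition_grid()] when `grid` is missing.
#' @return A data frame with `size`, `condition`, `rep`, `frc_true_ml`,
#'   `frc_est_ml` and `abs_err_pct`.
#' @export
run_condition_grid <- function(grid = NULL, replicates = 6, seed = 1) {
  if (is.null(grid)) grid <- condition_grid(replicates, seed)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- grid$config[[i]]
    rec <- simulate_recording(cfg)
    acfg <- analysis_config(dead_space_ml = cfg$dead_space_ml,
                            tracer_fraction = cfg$tracer_fraction,
                            btps_mode = "none")
    fit <- analyze_recording(rec, acfg)
    frc_true <- sum(cfg$frc_ml)
    data.frame(size = grid$size[i], condition = grid$condition[i],
               rep = grid$rep[i], frc_true_ml = frc_true,
               frc_est_ml = fit$outcomes$frc_ml,
               abs_err_pct = 100 * abs(fit$outcomes$frc_ml - frc_true) /
                 frc_true)
  })
  do.call(rbind, res)
}

#' Per-condition FRC accuracy report
#'
#' @param errors Output of [run_condition_grid()].
#' @return A data frame with one row per condition cell plus an `overall` row:
#'   `condition`, `volume`, `n`, `mean_abs_err_pct`, `sd_abs_err_pct`.
#' @export
frc_accuracy_report <- function(errors) {
  key <- interaction(errors$condition, errors$size, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    e <- errors[key == k, ]
    data.frame(condition = e$condition[1], volume = e$size[1],
               n = nrow(e), mean_abs_err_pct = mean(e$abs_err_pct),
               sd_abs_err_pct = stats::sd(e$abs_err_pct))
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(condition = "overall", volume = "all",
                        n = nrow(errors),
                        mean_abs_err_pct = mean(errors$abs_err_pct),
                        sd_abs_err_pct = stats::sd(errors$abs_err_pct)))
}
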