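# Shared simulation fixtures, built in code and cached for the test run.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, cfg) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- simulate_recording(cfg)
  .sim_cache[[key]]
}

# noiseless single-compartment run at the small lung-model geometry
exact_small_cfg <- function(...) {
  args <- utils::modifyList(
    list(frc_ml = 80, vt_ml = 30, rr_bpm = 30, dead_space_ml = 4.6,
         chamber_fraction = 0, noise_sd_gmol = 0,
         tidal_temp_amp_k = 0, humidity_tidal = FALSE, seed = 7),
    list(...))
  do.call(simulation_config, args)
}

# default (noisy, chambered, confounded) small run
noisy_small_cfg <- function(...) {
  args <- utils::modifyList(
    list(frc_ml = 80, vt_ml = 30, rr_bpm = 30, dead_space_ml = 4.6,
         seed = 11),
    list(...))
  do.call(simulation_config, args)
}

atp_config <- function(dead_space_ml = 4.6, ...) {
  analysis_config(dead_space_ml = dead_space_ml, btps_mode = "none", ...)
}

# closed-form single-compartment washout: with dead-space re-breathing the
# end-tidal concentration decays by r = (FRC + VD) / (FRC + VT) per breath
dilution_ratio <- function(frc, vt, vd) (frc + vd) / (frc + vt)
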