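# The 10 cells of the in-vitro lung-model condition grid (one replicate
# each). Replicated runs with distinct seeds are produced by
# condition_grid() / run_condition_grid(); this file drives the CLI
# `simulate` subcommand.
scenarios:
  - {name: small_standard, frc_ml: 80, vt_ml: 30, rr_bpm: 30, dead_space_ml: 4.6, tidal_temp_amp_k: 2.85}
  - {name: small_-T,       frc_ml: 80, vt_ml: 30, rr_bpm: 30, dead_space_ml: 4.6, tidal_temp_amp_k: -0.9}
  - {name: small_+RR,      frc_ml: 80, vt_ml: 30, rr_bpm: 50, dead_space_ml: 4.6, tidal_temp_amp_k: 2.85}
  - {name: small_+VT,      frc_ml: 80, vt_ml: 50, rr_bpm: 30, dead_space_ml: 4.6, tidal_temp_amp_k: 2.85}
  - {name: small_+VI,      frc_ml: [40, 40], vent_frac: [0.7, 0.3], vt_ml: 30, rr_bpm: 30, dead_space_ml: 4.6, tidal_temp_amp_k: 2.85}
  - {name: large_standard, frc_ml: 210, vt_ml: 50, rr_bpm: 20, dead_space_ml: 9.6, tidal_temp_amp_k: 2.85}
  - {name: large_-T,       frc_ml: 210, vt_ml: 50, rr_bpm: 20, dead_space_ml: 9.6, tidal_temp_amp_k: -0.9}
  - {name: large_+RR,      frc_ml: 210, vt_ml: 50, rr_bpm: 30, dead_space_ml: 9.6, tidal_temp_amp_k: 2.85}
  - {name: large_+VT,      frc_ml: 210, vt_ml: 80, rr_bpm: 20, dead_space_ml: 9.6, tidal_temp_amp_k: 2.85}
  - {name: large_+VI,      frc_ml: [105, 105], vent_frac: [0.7, 0.3], vt_ml: 50, rr_bpm: 20, dead_space_ml: 9.6, tidal_temp_amp_k: 2.85}
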