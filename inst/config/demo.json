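{
  "simulate": {
    "fs": 2500,
    "duration": 60,
    "f_resp": 1.5,
    "f_hfo": 105,
    "burst_rate": 1.5,
    "coupling_kappa": 8,
    "lock_phase": 0.7853981633974483,
    "n_channels": 32,
    "spacing_um": 100,
    "depth_first_um": 100,
    "hfo_dipole_depth": 1600,
    "delta_dipole_depth": 2400,
    "mua_rate": 300
  },
  "spectra": { "welch_window_s": 20 },
  "coupling": {
    "phase_centers": [0.75, 1.5, 2.5, 3.5],
    "phase_bandwidth": 1,
    "amp_centers": [65, 85, 105, 125],
    "amp_bandwidth": 20,
    "n_bins": 18
  },
  "stats": {
    "n_subjects": 6,
    "subject_duration": 20,
    "scalers": { "delta": 1, "gamma": 0.25, "hfo": 4 }
  }
}
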