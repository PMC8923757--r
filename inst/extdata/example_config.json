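{
  "seed": 7,
  "geometry": {
    "num_elements": 64,
    "pitch": 0.154,
    "center_frequency": 5e6,
    "sampling_frequency": 4e7,
    "sound_speed": 1540
  },
  "pulse": {
    "center_frequency": 5e6,
    "fractional_bandwidth": 0.6,
    "duration_cycles": 4
  },
  "phantom": {
    "type": "cyst",
    "cyst_center": [0, 17],
    "cyst_radius": 2,
    "field_extent": {"x": [-5, 5], "z": [12, 22]},
    "speckle_density": 4,
    "noise_db": -30
  },
  "beamformer": {
    "method": "ISCB",
    "threshold_factor": 0.5
  },
  "grid": {"x": [-4, 4], "z": [13.5, 20.5], "step": 0.2},
  "metrics": {
    "dynamic_range": 60,
    "center_region": {"shape": "disc", "center": [0, 17], "radius": 1.2},
    "background_region": {"shape": "rect", "center": [3, 17], "half_extents": [0.5, 1.25]}
  },
  "benchmark": {"methods": ["DAS", "SCB", "ISCB"], "n_seeds": 3}
}
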