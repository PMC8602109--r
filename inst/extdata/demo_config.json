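{
  "n_residues": 14,
  "atoms_per_residue": 3,
  "n_frames": 240,
  "frame_stride": 1,
  "n_replicas": 2,
  "systems": ["sysA", "sysB"],
  "states": ["apo", "holo", "holo+ATP"],
  "mode_lambda": [1.0, 0.25],
  "noise_sigma": 0.15,
  "state_scale": {"apo": 1.0, "holo": 0.85, "holo+ATP": 0.55},
  "displaced_block": [11, 12, 13],
  "displacement": [0, 3.5, 0],
  "window": {"last_frames": 120},
  "contact_cutoff": 5.0,
  "dpn_threshold": 5.0,
  "sieve": 10,
  "k": 4,
  "ed_modes": 4,
  "rmsip_modes": 3,
  "wisp": {"source": 2, "sink": 13, "delta": 1.0},
  "site": {"residues": [11, 12, 13]},
  "seed": 1
}
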