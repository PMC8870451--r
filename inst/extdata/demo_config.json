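{
  "outdir": "ionpocket_demo",
  "seed": 20220224,
  "stages": ["simulate", "shells", "rotamers", "hbonds", "amd", "pb_bind", "phylo"],
  "analysis": {},
  "pb": {"grid_points": 33, "scale": 1.2, "ionic_strength": 0.15},
  "trajectory": {"n_replicas": 3, "n_frames": 60, "frame_interval": 1, "noise_sd": 0.03},
  "amd": {"mean": [500, -50000], "sd": [10, 200], "n": 1300, "dt": 0.1,
          "window": [20, 120], "lambda": 0.3, "n_atoms": 10000},
  "pb_bind": {"snapshots_per_traj": 3},
  "phylo": {"n_reps": 50, "threshold": 0.9}
}
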