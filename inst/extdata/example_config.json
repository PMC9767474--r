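{
  "map": {
    "bbox": [40, 52, 0, 16],
    "resolution": 1,
    "topography": "synthetic_topography.asc",
    "snap_radius": 1
  },
  "model": {
    "variant": "B",
    "allele_age_years_bp": 7250,
    "generation_time": 29,
    "epoch_boundary_years_bp": 3480,
    "founder_density_D": 2.5,
    "origin": [46.5, 8.5],
    "epochs": [0.06, 40, 25, 0.03, 60, 40]
  },
  "samples": "example_samples.tsv",
  "bounds": {
    "s": [0.001, 0.1],
    "sigma2": [1, 100],
    "v": [-2.5, 2.5]
  },
  "optimizer": {
    "n_starts": 4,
    "output_dt": 5,
    "sa": {
      "iters": 40
    },
    "refine": {
      "maxit": 40
    }
  }
}
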