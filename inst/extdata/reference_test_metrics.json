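{
  "comment": "Reference fit statistics for Chinese fir individual-tree growth models on Fujian CFI data (train/test metrics per covariate-ladder rung for the network and forest diameter models; whole-model metrics for the height models). DBH metrics in cm, H metrics in m. Shipped as inputs for comparative arithmetic; the underlying inventory data are not public.",
  "dbh_bp": {
    "variables": ["T", "T + Comp", "T + Comp + Site", "T + Comp + Site + Clim"],
    "train_r2":   [0.669, 0.721, 0.809, 0.831],
    "train_mae":  [2.041, 1.836, 1.463, 1.342],
    "train_rmse": [2.626, 2.375, 1.973, 1.824],
    "test_r2":    [0.638, 0.689, 0.776, 0.808],
    "test_mae":   [2.164, 1.962, 1.614, 1.487],
    "test_rmse":  [2.745, 2.506, 2.141, 2.017]
  },
  "dbh_rf": {
    "variables": ["T", "T + Comp", "T + Comp + Site", "T + Comp + Site + Clim"],
    "train_r2":   [0.714, 0.782, 0.827, 0.867],
    "train_mae":  [1.893, 1.593, 1.368, 1.201],
    "train_rmse": [2.391, 2.104, 1.866, 1.573],
    "test_r2":    [0.679, 0.733, 0.826, 0.849],
    "test_mae":   [1.997, 1.782, 1.387, 1.267],
    "test_rmse":  [2.537, 2.281, 1.871, 1.691]
  },
  "dbh_rp": { "test_r2": 0.621, "test_rmse": 2.813 },
  "h_rp":   { "test_r2": 0.683, "test_rmse": 2.102 },
  "h_bp":   { "test_r2": 0.731, "test_rmse": 1.857, "test_mae": 1.686 },
  "h_rf":   { "test_r2": 0.845, "test_rmse": 1.267, "test_mae": 1.153 }
}
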