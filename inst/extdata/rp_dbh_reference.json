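{
  "response_kind": "DBH",
  "comment": "Reference coefficient estimates for the covariate-parameterized Mitscherlich diameter model, Chinese fir, Fujian Province CFI plots. Units: alpha in cm per covariate unit, beta in 1/year per covariate unit. The DM rate coefficient is 0.000 as printed in the source table.",
  "variables": ["N", "PW", "HB", "TRHD", "DM", "DD18", "Eref"],
  "alpha": [-20.041, 0.001, -0.096, -0.004, 0.155, -1.525, 0.001, 0.031],
  "beta": [0.039, 5.89e-06, -4.11e-05, 4.01e-06, -6.17e-06, 0.0, 4.79e-06, -7.63e-06]
}
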