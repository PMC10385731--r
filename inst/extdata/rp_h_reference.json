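{
  "response_kind": "H",
  "comment": "Reference coefficient estimates for the covariate-parameterized Mitscherlich height model, Chinese fir, Fujian Province CFI plots. Units: alpha in m per covariate unit, beta in 1/year per covariate unit. The DM rate coefficient is 0.000 as printed in the source table.",
  "variables": ["N", "PW", "HB", "TRHD", "DM", "DD18", "Eref"],
  "alpha": [-2.301, 0.014, 0.625, -0.002, 0.095, 1.737, -0.011, 0.012],
  "beta": [0.063, 9.62e-07, -6.83e-05, -1.62e-06, 4.68e-05, 0.0, -1.01e-05, 2.63e-05]
}
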