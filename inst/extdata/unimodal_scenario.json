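{
  "test": { "theta0": 0, "alpha": 0.05, "sigma2": 4 },
  "priors": [
    { "type": "point", "theta_d": 0.372 },
    { "type": "normal", "theta_d": 0.198, "n_d": 46 },
    { "type": "normal", "theta_d": 0.198, "n_d": 46,
      "variance_prior": { "shape": 16, "scale": 60 } },
    { "type": "skew_normal", "theta_d": 0.198, "n_d": 46, "lambda": 1 },
    { "type": "trunc_normal", "theta_d": 0.198, "n_d": 46, "lower": 0 },
    { "type": "mixture", "w0": 0.5,
      "components": [ { "theta_d": 0, "n_d": 165 },
                      { "theta_d": 0.545, "n_d": 46 } ] }
  ],
  "evaluation": { "n": [100, 500], "method": "mc", "M": 1e6, "seed": 1 },
  "ssd": { "fraction": 0.8, "measures": ["u", "a", "b", "c"], "n_max": 1e6 }
}
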