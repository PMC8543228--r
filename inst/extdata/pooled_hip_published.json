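{
  "description": "Pooled compositional Cox coefficients for waking-day ilr balances from hip-accelerometer mortality cohorts (device-stratified random-effects pooling); 95% Wald bounds as published.",
  "stratum": "hip",
  "gamma": {"z2": -0.073, "z3": -0.681},
  "ci_lower": {"z2": -0.143, "z3": -0.875},
  "ci_upper": {"z2": -0.003, "z3": -0.486}
}
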