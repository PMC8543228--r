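{
  "description": "Pooled compositional Cox coefficients for 24-h ilr balances from wrist-accelerometer mortality cohorts (device-stratified random-effects pooling); 95% Wald bounds as published.",
  "stratum": "wrist",
  "gamma": {"z1": -0.144, "z2": -0.465, "z3": -0.041},
  "ci_lower": {"z1": -0.402, "z2": -0.588, "z3": -0.415},
  "ci_upper": {"z1": 0.114, "z2": -0.342, "z3": 0.333}
}
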