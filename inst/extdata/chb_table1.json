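{
  "analyte": "cHb",
  "unit": "g/dL",
  "parameters": [-0.3409, 0.83, -0.0093, 0.0003, 0.0058],
  "offset": 3.76,
  "domain_ga": [22, 42],
  "domain_pna": [0, 28],
  "provenance": "published tied bi-quadratic fit to a digitized neonatal reference grid"
}
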