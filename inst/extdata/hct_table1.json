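{
  "analyte": "Hct",
  "unit": "%",
  "parameters": [-1.2956, 2.5369, -0.03, 0.0069, 0.019],
  "offset": 10.69,
  "domain_ga": [22, 42],
  "domain_pna": [0, 28],
  "provenance": "published tied bi-quadratic fit to a digitized neonatal reference grid"
}
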