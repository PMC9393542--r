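{
  "Cr": {"rfd": 1.5, "sf": 0.5, "standard_limit": 1.0, "carcinogenic": true},
  "Ni": {"rfd": 0.02, "sf": null, "standard_limit": 1.0, "carcinogenic": false},
  "As": {"rfd": 0.0003, "sf": 1.5, "standard_limit": 0.5, "carcinogenic": true},
  "Cd": {"rfd": 0.001, "sf": 0.38, "standard_limit": 0.2, "carcinogenic": true},
  "Pb": {"rfd": 0.0035, "sf": 0.0085, "standard_limit": 0.2, "carcinogenic": true},
  "F": {"rfd": 0.06, "sf": null, "standard_limit": null, "carcinogenic": false}
}
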