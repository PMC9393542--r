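{
  "n_samples": 149,
  "elements": ["Cr", "Ni", "As", "Cd", "Pb", "F"],
  "marginals": {
    "Cr": {
      "family": "lnorm_mix2",
      "w": 0.59798,
      "meanlog1": -0.43691,
      "sdlog1": 0.85243,
      "meanlog2": 1.89582,
      "sdlog2": 0.15433
    },
    "Ni": {
      "family": "lognormal",
      "meanlog": -0.73076,
      "sdlog": 0.83781
    },
    "As": {
      "family": "lognormal",
      "meanlog": -2.92003,
      "sdlog": 0.19804
    },
    "Cd": {
      "family": "lognormal",
      "meanlog": -2.12133,
      "sdlog": 0.65957
    },
    "Pb": {
      "family": "lognormal",
      "meanlog": -3.6164,
      "sdlog": 0.86279
    },
    "F": {
      "family": "lognormal",
      "meanlog": 1.42746,
      "sdlog": 0.41291
    }
  },
  "clip": {
    "Cr": [0.096, 8.546],
    "Ni": [0.0005, 5.034],
    "As": [0.036, 0.132],
    "Cd": [0.012, 0.538],
    "Pb": [0.001, 0.311],
    "F": [0.272, 9.73]
  },
  "target_spearman": [
    [1, 0.309, -0.222, 0, 0.472, 0],
    [0.309, 1, 0.107, 0.143, 0.228, 0],
    [-0.222, 0.107, 1, 0.12, -0.191, -0.081],
    [0, 0.143, 0.12, 1, 0.079, 0],
    [0.472, 0.228, -0.191, 0.079, 1, 0],
    [0, 0, -0.081, 0, 0, 1]
  ]
}
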