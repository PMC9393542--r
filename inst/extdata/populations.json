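{
  "children": {"bw": 16.88, "ir": 0.094, "ed": 6, "ef": 365, "lifetime_years": 70},
  "adult_females": {"bw": 57.03, "ir": 0.160, "ed": 70, "ef": 365, "lifetime_years": 70},
  "adult_males": {"bw": 66.2, "ir": 0.160, "ed": 70, "ef": 365, "lifetime_years": 70}
}
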