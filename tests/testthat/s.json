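{
  "n_reaches": 0,
  "n_rewarded": 0,
  "n_punishments": 0,
  "rts": [],
  "median_rt": null,
  "moving_avg_rt5": [],
  "iri": [],
  "amp_threshold": 0.9,
  "expert": false
}
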