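{
  "n_reaches": 59,
  "n_rewarded": 22,
  "n_punishments": 0,
  "rts": [],
  "median_rt": null,
  "moving_avg_rt5": [],
  "iri": [974, 596, 3869, 8069, 1811, 741, 2174, 522, 6797, 4346, 2392, 1195, 432, 1887, 1489, 1221, 3668, 3959, 3093, 1748, 685, 938, 459, 1476, 1562, 939, 1579, 911, 1252, 1979, 2944, 891, 3195, 609, 6675, 756, 1507, 708, 1063, 1179, 572, 1746, 3403, 2377, 994, 2875, 996, 1116, 2587, 922, 651, 2824, 4032, 994, 1171, 5109, 913, 2947],
  "amp_threshold": 0.5,
  "expert": false
}
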