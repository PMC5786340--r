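{
  "model": "ionic",
  "protocol": {"pcl": 300, "n_beats": 50},
  "params": {"tau_f": 45, "u": 3, "gamma": 0.7, "w": 0},
  "seed": 1,
  "stride": 5
}
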