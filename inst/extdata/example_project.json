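{
  "app": "rat2",
  "fps": 10,
  "seed": 101,
  "simulate": true,
  "duration_s": 120,
  "noise_sd": 3,
  "debounce": 3,
  "out_dir": "zootrack_out"
}
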