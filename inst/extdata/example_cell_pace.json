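{
  "kind": "cell-pace",
  "iso": 0.1,
  "seed": 1,
  "pcl": 1000,
  "n_beats": 1000,
  "mods": {},
  "curves": {}
}
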