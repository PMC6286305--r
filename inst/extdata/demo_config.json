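{
  "seed": 1,
  "outdir": "demo_out",
  "sasa": {"kind": "tm", "n_frames": 10, "n_points": 240},
  "gel": {
    "replicates": 3,
    "sigma": 0.15,
    "constructs": [
      {"name": "extended_like", "d50": 64},
      {"name": "tm_like", "d50": 70}
    ]
  }
}
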