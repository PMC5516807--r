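{
  "motifs": [
    {"A": 1, "B": 0},
    {"A": 0, "B": 1}
  ],
  "attractors": [
    {"kind": "steady_state", "states": [{"A": 1, "B": 0}]},
    {"kind": "steady_state", "states": [{"A": 0, "B": 1}]}
  ]
}
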