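{
  "region": "brain",
  "anchors": [
    {"age": 0,  "factor": 0.011},
    {"age": 1,  "factor": 0.0067},
    {"age": 5,  "factor": 0.0040},
    {"age": 10, "factor": 0.0032}
  ]
}
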