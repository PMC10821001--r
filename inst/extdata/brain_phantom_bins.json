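{
  "bins": [
    {"lower": 0,    "upper": 0.5,  "ratio": 0.0115},
    {"lower": 0.5,  "upper": 2.5,  "ratio": 0.0076},
    {"lower": 2.5,  "upper": 7.5,  "ratio": 0.0047},
    {"lower": 7.5,  "upper": 12.5, "ratio": 0.0036},
    {"lower": 12.5, "upper": 15,   "ratio": 0.0028}
  ]
}
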