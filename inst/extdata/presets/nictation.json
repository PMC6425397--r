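{
  "name": "nictation",
  "stimuli_nA": {"IL2DL": 2.0, "IL2DR": 2.0, "IL2L": 2.0, "IL2R": 2.0,
                 "IL2VL": 2.0, "IL2VR": 2.0},
  "ablated": []
}
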