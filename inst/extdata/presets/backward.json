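{
  "name": "backward",
  "stimuli_nA": {"ALML": 5.8, "ALMR": 5.8, "AVAL": 2.0, "AVAR": 2.0,
                 "AVDL": 1.0, "AVDR": 1.0, "AVEL": 1.0, "AVER": 1.0},
  "ablated": []
}
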