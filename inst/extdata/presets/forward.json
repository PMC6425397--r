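{
  "name": "forward",
  "stimuli_nA": {"PLML": 1.4, "PLMR": 1.4, "AVBL": 2.3, "AVBR": 2.3},
  "ablated": []
}
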