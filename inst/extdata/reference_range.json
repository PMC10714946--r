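{
  "auc_0_168": [43459, 63467],
  "cmax": [305.7, 488.3],
  "tmax": [24, 72]
}
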