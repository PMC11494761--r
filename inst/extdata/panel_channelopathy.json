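{
  "name": "channelopathy",
  "genes": ["SCN5A", "CACNA1C", "KCNQ1", "KCNH2", "CASQ2"]
}
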