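{
  "name": "aortic",
  "genes": ["FBN1", "ELN", "LOX", "EFEMP2", "MFAP5"]
}
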