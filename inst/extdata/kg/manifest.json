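{
  "cardiomyopathy": {
    "entity": 16,
    "location": 13,
    "pathway": 3,
    "structural": 20
  },
  "channelopathy": {
    "entity": 8,
    "location": 8,
    "pathway": 6,
    "structural": 10
  },
  "aortic": {
    "entity": 8,
    "location": 4,
    "pathway": 3,
    "structural": 10
  }
}
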