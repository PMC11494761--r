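{
  "name": "cardiomyopathy",
  "genes": ["TNNT2", "CAPZA1", "MYL1", "DES", "TTN", "ACTN1", "MYH7",
            "MYH6", "TPM1", "ACTC1", "TNNC1", "MYBPC3", "MYL2"]
}
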