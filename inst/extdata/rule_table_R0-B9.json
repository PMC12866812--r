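{
  "scheme": "R0-B9",
  "unit_len": 2,
  "radix": 9,
  "max_run": 1,
  "initiator": "AT",
  "guard": true,
  "rows": {
    "A": ["TA", "TG", "GA", "GC", "GT", "CT", "CG", "TC", "CA"],
    "C": ["AT", "GT", "TG", "AC", "GC", "TA", "AG", "TC", "GA"],
    "G": ["AG", "CT", "TG", "TA", "CA", "AT", "AC", "CG", "TC"],
    "T": ["AT", "CG", "GT", "CA", "GA", "GC", "AC", "AG", "CT"]
  }
}
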