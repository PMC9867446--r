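{
  "synthetic": true,
  "note": "Synthetic CLC scaffold generated by clc_blueprint(); stand-in for a real anchor reference such as EcCLC.",
  "gating": 180,
  "proton": 246,
  "filter_start": 144,
  "filter_len": 6
}
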