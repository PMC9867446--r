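{
  "GxGxPE": "GxGxPE",
  "GKxGPxxH": "GKxGPxxH",
  "PxxGxLF": "PxxGxLF",
  "YXXphi": "Yxxh",
  "DXXLL": "DxxLL",
  "DE_XXXL_LI": "[DE]xxxL[LI]"
}
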