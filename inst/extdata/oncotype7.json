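{
  "name": "Oncotype DX colon 7-gene set (RS_U-sign directions)",
  "genes": ["BGN", "FAP", "INHBA", "GADD45B", "MYBL2", "KI67", "MYC"],
  "directions": ["unfavorable", "unfavorable", "unfavorable", "unfavorable",
                 "favorable", "favorable", "favorable"]
}
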