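{
  "name": "15-gene relapse signature",
  "genes": ["BET1L", "CD2BP2", "CD40LG", "JUP", "KCND2", "SNAPC5",
            "TMEM86B", "TRIP10", "ZNF785",
            "ATOH1", "FAM173B", "GGT6", "MTF1", "TBC1D3H", "UNC13B"],
  "directions": ["unfavorable", "unfavorable", "unfavorable", "unfavorable",
                 "unfavorable", "unfavorable", "unfavorable", "unfavorable",
                 "unfavorable",
                 "favorable", "favorable", "favorable", "favorable",
                 "favorable", "favorable"]
}
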