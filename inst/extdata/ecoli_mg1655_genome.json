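{
  "name": "E. coli K-12 MG1655",
  "length_bp": 4641652,
  "ori_position_bp": 3925744,
  "n_bins": 46
}
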