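{
  "design": "binary",
  "comment": "CT (test 1) and MRI (test 2) for lung cancer risk; rows indexed by test 1 = 0,1 and columns by test 2 = 0,1",
  "s": [[3, 9], [12, 14]],
  "r": [[18, 13], [9, 4]],
  "u": [[10, 9], [8, 7]]
}
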