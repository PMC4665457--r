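{
  "design": "binary",
  "comment": "CT and MRI for lung cancer risk with extreme verification bias: every subject positive on at least one test is verified, no double-negative subject is",
  "s": [[0, 9], [12, 14]],
  "r": [[0, 13], [9, 4]],
  "u": [[21, 0], [0, 0]]
}
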