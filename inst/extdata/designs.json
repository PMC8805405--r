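{
  "light": [
    {"id": "A", "back_mutations": []},
    {"id": "B", "back_mutations": [[6, "S"]]},
    {"id": "C", "back_mutations": [[6, "S"], [40, "G"]]}
  ],
  "heavy": [
    {"id": "a", "back_mutations": []},
    {"id": "b", "back_mutations": [[11, "V"]]},
    {"id": "c", "back_mutations": [[11, "V"], [70, "R"]]}
  ]
}
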