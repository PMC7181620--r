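[
  {"experiment": 3, "config": 1, "means": [[-3, 0], [0, 0], [3, 0]], "sd": 2},
  {"experiment": 3, "config": 2, "means": [[-4, 0], [0, 0], [4, 0]], "sd": 2},
  {"experiment": 3, "config": 3, "means": [[-3, 0], [-2, 0], [3, 0]], "sd": 2},
  {"experiment": 3, "config": 4, "means": [[-3, 0], [2, 0], [3, 0]], "sd": 2}
]
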