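[
  {"experiment": 2, "config": 1, "means": [[-2, 1.16], [0, -2.31], [2, 1.16]], "sd": 2},
  {"experiment": 2, "config": 2, "means": [[-1.59, 0.94], [0, -1.84], [1.59, 0.94]], "sd": 2},
  {"experiment": 2, "config": 3, "means": [[-2, 1.16], [-2, 0], [2, 1.16]], "sd": 2},
  {"experiment": 2, "config": 4, "means": [[-2, 1.16], [2, 0], [2, 1.16]], "sd": 2}
]
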