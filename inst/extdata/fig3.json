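{
  "leaves": {
    "1": "x1",
    "2": "x2",
    "3": "x3",
    "4": "y4",
    "5": "y5",
    "6": "y6"
  },
  "tree_edges": [
    ["v1", "x1"],
    ["v2", "x2"],
    ["v3", "x3"],
    ["v3", "v2"],
    ["v3", "v4"],
    ["a", "v4"],
    ["a", "y4"],
    ["a", "b"],
    ["b", "y5"],
    ["b", "y6"]
  ],
  "reticulations": [
    {
      "head": "v1",
      "tails": ["v2", "v4"]
    }
  ]
}
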