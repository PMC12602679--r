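{
  "species": ["W", "Y", "Z"],
  "reactions": [
    {
      "reactants": {
        "Z": 1
      },
      "products": {
        "W": 1
      },
      "rate_constant": 0.5
    },
    {
      "reactants": {
        "W": 1
      },
      "products": {
        "Y": 1
      },
      "rate_constant": 1
    }
  ],
  "initial_state": {
    "W": 0,
    "Y": 0,
    "Z": 2
  }
}
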