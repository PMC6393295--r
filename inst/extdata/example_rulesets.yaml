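# Example declarative rule-set configuration. Ordered base pairs are
# written "base5:base3"; null / omitted fields are unconstrained.
rulesets:
  - name: archaeal-NSun6
    required_cca: true
    required_n72: [C]
    allowed_n73: [U, G]
    required_pair_2_71: ["C:G"]
  - name: human-NSun6-with-D-stem
    required_cca: true
    required_n72: [C]
    allowed_n73: [U]
    required_pair_2_71: ["G:C"]
    required_d_stem_pairs:
      "11:24": ["C:G", "U:A"]
      "12:23": ["C:G", "U:A"]
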