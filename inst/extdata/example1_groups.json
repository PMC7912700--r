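{"groups": {"arts": ["X1", "X2", "X3"], "science": ["X4", "X5"]}}
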