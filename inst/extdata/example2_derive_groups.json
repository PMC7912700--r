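{"groups": {"problem": ["X2", "X3", "X4"], "verbal": ["X5", "X6"]}}
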