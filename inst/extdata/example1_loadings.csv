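variable,f1,f2
X1,0.60,0.39
X2,0.75,0.24
X3,0.65,0.00
X4,0.32,0.59
X5,0.00,0.92
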