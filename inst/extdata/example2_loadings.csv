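variable,f1,f2
X1,0.64,0.37
X2,0.34,0.54
X3,0.46,0.76
X4,0.25,0.41
X5,0.97,-0.12
X6,0.82,-0.03
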