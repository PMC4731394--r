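id,f1,f2
a,1.0,0.1
b,0.9,0.2
c,1.1,0.0
d,0.1,1.0
e,0.2,0.9
f,0.0,1.1
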