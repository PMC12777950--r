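Y,T,X1
3,1,0
5,1,0.2
1,0,0.1
3,0,0.3
8,1,10
6,1,10.2
5,0,10.1
3,0,10.3
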