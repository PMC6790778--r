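x,y
0.5,1.1
1.3,2.3
2.2,2.9
3.1,4.8
4.7,5.6
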