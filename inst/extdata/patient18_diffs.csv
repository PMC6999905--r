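time,series,value
1,diff,0.64
2,diff,1.08
3,diff,-0.36
4,diff,0.79
5,diff,-0.64
6,diff,1.50
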