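time,series,value
1,A,92
2,A,76
3,A,68
4,A,58
5,A,50
6,A,38
7,A,18
8,A,2
1,B,98
2,B,92
3,B,90
4,B,84
5,B,72
6,B,56
7,B,2
8,B,2
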