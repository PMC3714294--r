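upper_bound,color
0,#FFFFFF
1,#4575B4
2,#74ADD1
4,#ABD9E9
8,#FEE090
16,#FDAE61
32,#F46D43
64,#D73027
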