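semitone_offset,value
0,6.35
1,2.23
2,3.48
3,2.33
4,4.38
5,4.09
6,2.52
7,5.19
8,2.39
9,3.66
10,2.29
11,2.88
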