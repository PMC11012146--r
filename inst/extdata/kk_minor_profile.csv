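semitone_offset,value
0,6.33
1,2.68
2,3.52
3,5.38
4,2.60
5,3.53
6,2.54
7,4.75
8,3.98
9,2.69
10,3.34
11,3.17
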