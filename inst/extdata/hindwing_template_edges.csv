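from,to
1,2
1,14
1,10
14,3
3,4
4,5
5,6
14,11
11,12
12,13
13,6
10,9
9,8
8,7
7,6
11,9
12,8
2,3
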