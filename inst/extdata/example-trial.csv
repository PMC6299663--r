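cohort,dose_level,n,y
1,1,3,1
2,1,3,0
3,2,3,0
4,3,3,1
5,4,3,0
6,5,3,0
7,6,3,1
8,5,3,1
9,6,3,3
10,5,3,1
11,5,3,2
12,5,3,1
13,4,3,0
14,5,3,1
15,5,3,0
16,5,3,1
17,5,3,1
18,5,3,2
19,4,3,0
20,5,3,0
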