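run,A,B,C,D,soluble_starch,yeast,nh4cl,fecl3,response
1,0,0,0,0,1.2,2.5,1.5,0.8,1.81
2,0,0,0,0,1.2,2.5,1.5,0.8,1.84
3,0,0,0,0,1.2,2.5,1.5,0.8,1.87
4,0,0,0,0,1.2,2.5,1.5,0.8,1.86
5,0,0,0,0,1.2,2.5,1.5,0.8,1.83
6,0,1,0,1,1.2,3,1.5,0.9,1.64
7,0,-1,0,1,1.2,2,1.5,0.9,1.75
8,0,1,0,-1,1.2,3,1.5,0.7,1.5
9,0,-1,0,-1,1.2,2,1.5,0.7,1.58
10,1,0,1,0,1.4,2.5,2,0.8,1.67
11,-1,0,1,0,1,2.5,2,0.8,1.88
12,1,0,-1,0,1.4,2.5,1,0.8,1.58
13,-1,0,-1,0,1,2.5,1,0.8,1.68
14,0,1,1,0,1.2,3,2,0.8,1.63
15,0,-1,1,0,1.2,2,2,0.8,1.74
16,0,1,-1,0,1.2,3,1,0.8,1.52
17,0,-1,-1,0,1.2,2,1,0.8,1.63
18,1,0,0,1,1.4,2.5,1.5,0.9,1.62
19,-1,0,0,1,1,2.5,1.5,0.9,1.71
20,1,0,0,-1,1.4,2.5,1.5,0.7,1.68
21,-1,0,0,-1,1,2.5,1.5,0.7,1.66
22,0,0,1,1,1.2,2.5,2,0.9,1.82
23,0,0,-1,1,1.2,2.5,1,0.9,1.75
24,0,0,1,-1,1.2,2.5,2,0.7,1.68
25,0,0,-1,-1,1.2,2.5,1,0.7,1.65
26,1,1,0,0,1.4,3,1.5,0.8,1.54
27,-1,1,0,0,1,3,1.5,0.8,1.53
28,1,-1,0,0,1.4,2,1.5,0.8,1.5
29,-1,-1,0,0,1,2,1.5,0.8,1.75
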