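"index","x_deg","y_deg","is_blind_spot"
1,9,21,FALSE
2,3,21,FALSE
3,-3,21,FALSE
4,-9,21,FALSE
5,15,15,FALSE
6,9,15,FALSE
7,3,15,FALSE
8,-3,15,FALSE
9,-9,15,FALSE
10,-15,15,FALSE
11,21,9,FALSE
12,15,9,FALSE
13,9,9,FALSE
14,3,9,FALSE
15,-3,9,FALSE
16,-9,9,FALSE
17,-15,9,FALSE
18,-21,9,FALSE
19,21,3,FALSE
20,15,3,TRUE
21,9,3,FALSE
22,3,3,FALSE
23,-3,3,FALSE
24,-9,3,FALSE
25,-15,3,FALSE
26,-21,3,FALSE
27,-27,3,FALSE
28,21,-3,FALSE
29,15,-3,TRUE
30,9,-3,FALSE
31,3,-3,FALSE
32,-3,-3,FALSE
33,-9,-3,FALSE
34,-15,-3,FALSE
35,-21,-3,FALSE
36,-27,-3,FALSE
37,21,-9,FALSE
38,15,-9,FALSE
39,9,-9,FALSE
40,3,-9,FALSE
41,-3,-9,FALSE
42,-9,-9,FALSE
43,-15,-9,FALSE
44,-21,-9,FALSE
45,15,-15,FALSE
46,9,-15,FALSE
47,3,-15,FALSE
48,-3,-15,FALSE
49,-9,-15,FALSE
50,-15,-15,FALSE
51,9,-21,FALSE
52,3,-21,FALSE
53,-3,-21,FALSE
54,-9,-21,FALSE
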