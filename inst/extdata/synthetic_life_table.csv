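age_start,age_end,q5
0,5,0.0450
5,10,0.0100
10,15,0.0080
15,20,0.0110
20,25,0.0150
25,30,0.0190
30,35,0.0230
35,40,0.0280
40,45,0.0350
45,50,0.0450
50,55,0.0600
55,60,0.0800
60,65,0.1100
65,70,0.1600
70,75,0.2300
75,80,0.3300
80,85,0.4600
85,90,0.6200
90,95,0.7800
95,100,0.9000
100,105,0.9700
105,110,0.9950
110,Inf,1
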