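age_lo	age_hi	rate_per_100k
0	20	0
20	25	1.5
25	30	9
30	35	27
35	40	56
40	45	110
45	50	160
50	55	190
55	60	215
60	65	255
65	70	290
70	75	300
75	80	280
80	85	260
85	90	240
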