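age_lo	age_hi	rate_per_100k
0	5	60
5	10	8
10	15	10
15	20	25
20	25	25
25	30	30
30	35	35
35	40	45
40	45	65
45	50	100
50	55	160
55	60	260
60	65	420
65	70	700
70	75	1200
75	80	2100
80	85	3900
85	90	7500
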