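frame_index	time_ps	dS	U_kJ_per_mol
0	0	0	-0.20000000000000001
1	0.050000000000000003	-0.25198109013454062	-0.29847664734519597
2	0.10000000000000001	-0.17848483815240068	-0.38304971107920383
3	0.14999999999999999	0.18072030042890477	-0.42669440101419903
4	0.20000000000000001	0.017277884438188517	-0.30818957732021829
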