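frame_index	time_ps	dS	U_kJ_per_mol
0	0	0	-0.20000000000000001
1	0.050000000000000003	-0.31124826079411094	-0.30463763015315826
2	0.10000000000000001	0.13722087070502104	-0.35969283953789966
3	0.14999999999999999	0.10940473083656482	-0.25110965575596444
4	0.20000000000000001	-0.025037398212010807	-0.069768726109910056
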