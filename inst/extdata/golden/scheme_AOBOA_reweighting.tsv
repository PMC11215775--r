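frame_index	time_ps	dS	U_kJ_per_mol
0	0	0	-0.20000000000000001
1	0.050000000000000003	-0.31123320016294304	-0.30270833067265002
2	0.10000000000000001	0.13721350881388672	-0.36095116521260728
3	0.14999999999999999	0.10939875969447597	-0.2623400273468261
4	0.20000000000000001	-0.025036647527723596	-0.074983536700695186
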