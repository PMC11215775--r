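frame_index	time_ps	dS	U_kJ_per_mol
0	0	0	-0.20000000000000001
1	0.050000000000000003	-0.31168376037108952	-0.30458117015500769
2	0.10000000000000001	0.13759565728354128	-0.35959442787110224
3	0.14999999999999999	0.11117342759544085	-0.25099171387138469
4	0.20000000000000001	-0.026103915584308177	-0.069657305323430785
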