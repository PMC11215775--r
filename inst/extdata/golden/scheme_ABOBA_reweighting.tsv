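frame_index	time_ps	dS	U_kJ_per_mol
0	0	0	-0.20000000000000001
1	0.050000000000000003	-0.25442603543610925	-0.3035561312875556
2	0.10000000000000001	-0.18018742206547764	-0.38753036139097169
3	0.14999999999999999	0.18264592908774729	-0.41135219383216071
4	0.20000000000000001	0.017552635186919595	-0.28395588791894388
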