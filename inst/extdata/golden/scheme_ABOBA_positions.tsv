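frame_index	time_ps	q_1
0	0	0.10000000000000001
1	0.050000000000000003	0.1517780656437778
2	0.10000000000000001	0.19376518069548584
3	0.14999999999999999	0.20567609691608035
4	0.20000000000000001	0.14197794395947194
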