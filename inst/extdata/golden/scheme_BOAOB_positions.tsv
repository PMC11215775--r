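frame_index	time_ps	q_1
0	0	0.10000000000000001
1	0.050000000000000003	0.15231881507657913
2	0.10000000000000001	0.17984641976894983
3	0.14999999999999999	0.12555482787798222
4	0.20000000000000001	0.034884363054955028
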