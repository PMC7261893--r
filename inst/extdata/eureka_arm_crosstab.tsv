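arm2	arm1_0	arm1_1	arm1_2	arm1_3	arm1_4	arm1_5
0	5	3	1	0	0	0
1	6	4	1	0	1	0
2	6	2	1	0	0	1
3	1	1	0	0	0	0
4	1	0	0	0	0	0
5	0	0	0	0	0	0
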