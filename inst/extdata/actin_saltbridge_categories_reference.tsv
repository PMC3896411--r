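pressure_MPa	label	inter_helix_strand	helix_strand_loop	loop_loop	intra_helix_strand	atp	inter_subdomain	intra_subdomain	total
0.1	Rab	16.4	9.9	0.0	11.3	2.5	10.2	27.4	40.2
0.1	Ac1W	14.7	6.9	0.2	6.8	2.2	8.0	20.5	30.7
0.1	Ac1Q	11.9	8.4	0.4	6.7	1.8	7.4	20.0	29.2
0.1	Ac2	12.8	8.5	0.7	8.0	2.4	7.0	23.0	32.4
0.1	Arm	20.5	9.2	1.0	8.9	2.7	10.7	28.9	42.4
0.1	Yaq	19.1	9.0	0.1	9.5	3.7	11.1	26.6	41.4
60	Rab	15.9	11.2	0.0	11.6	2.1	9.2	29.4	40.8
60	Ac1W	15.7	9.9	0.0	6.4	2.4	8.2	23.8	34.4
60	Ac1Q	14.1	8.9	0.0	7.9	2.3	7.9	23.1	34.2
60	Ac2	14.7	11.1	2.3	9.0	1.3	9.1	28.0	38.4
60	Arm	19.4	11.1	0.0	8.3	3.3	11.5	27.4	42.2
60	Yaq	18.8	11.8	0.2	8.4	2.8	10.5	28.7	41.9
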