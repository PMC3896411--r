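pressure_MPa	label	K18_O_alpha	K18_O_beta	K137_O_gamma	total
0.1	Rab	1.0	1.5	NA	2.5
0.1	Ac1W	0.8	1.4	NA	2.2
0.1	Ac1Q	0.7	1.1	NA	1.8
0.1	Ac2	1.0	1.4	NA	2.4
0.1	Arm	1.0	0.6	1.1	2.7
0.1	Yaq	1.0	1.0	1.7	3.7
60	Rab	1.0	1.1	NA	2.1
60	Ac1W	1.0	1.4	NA	2.4
60	Ac1Q	1.0	1.3	NA	2.3
60	Ac2	0.3	1.0	NA	1.3
60	Arm	1.0	0.9	1.4	3.3
60	Yaq	1.0	0.8	1.0	2.8
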