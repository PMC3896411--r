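label	delta_E_conf	sd_E	delta_delta_mu	sd_mu	T_delta_S	sd_TS	delta_G_printed	sd_G_printed	delta_delta_G_printed
Rab	-59	53	520	32	18	18	444	57	-135
Ac1W	11	103	532	14	16	26	527	122	-51
Ac1Q	16	85	575	43	13	15	579	65	0
Ac2	-52	127	512	29	19	24	441	112	-138
Arm	-147	67	510	22	29	20	334	69	-244
Yaq	-153	92	535	25	30	11	352	77	-226
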