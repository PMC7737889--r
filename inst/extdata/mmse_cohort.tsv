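diagnosis	age_bin	edu	mmse	o_time	o_place	reg	att_calc	del_rec	name	rep	read	write	vis_spat	comm
Mild AD	75-80	6	19	4	4	3	0	0	2	1	1	1	1	2
Mild AD	75-80	0	16	2	5	3	0	2	2	1	0	0	0	1
Mild AD	80-85	3	18	4	5	3	1	0	2	0	0	0	0	3
Mild AD	85-90	0	12	2	3	3	0	0	2	1	0	0	0	2
Mild AD	70-75	4	15	2	5	3	0	0	2	0	0	0	0	3
Mild AD	85-90	0	16	3	4	3	0	0	2	1	0	0	0	3
Mild AD	65-70	5	12	3	2	3	0	0	2	0	0	0	0	2
Mild AD	65-70	0	18	2	3	3	0	3	2	1	0	0	0	3
Mild AD	70-75	6	19	5	3	3	3	0	2	0	1	1	0	1
Mild AD	80-85	8	17	2	5	3	0	0	2	0	1	1	0	3
Mild AD	60-65	5	11	3	2	3	0	0	2	0	0	0	0	3
Normal	75-80	6	27	5	5	3	4	2	2	1	1	0	1	3
Normal	70-75	5	30	5	5	3	5	3	2	1	1	1	1	3
Normal	65-70	6	26	5	5	3	4	2	2	0	1	0	1	3
Normal	65-70	12	30	5	5	3	5	3	2	1	1	1	1	3
Normal	70-75	0	21	5	5	3	1	2	2	1	0	0	0	3
Normal	60-65	14	29	5	5	3	5	2	2	1	1	1	1	3
Normal	65-70	0	21	5	5	3	1	1	2	1	0	0	0	3
Normal	55-60	4	27	5	5	3	2	3	2	1	1	1	1	3
Normal	75-80	0	23	4	5	3	4	2	2	1	0	0	0	3
Normal	70-75	0	26	5	5	3	5	1	2	1	1	0	0	3
Normal	70-75	6	26	5	4	3	2	3	2	1	1	1	1	3
Normal	65-70	0	21	5	4	3	1	3	2	0	0	0	0	3
Normal	60-65	12	28	5	5	3	3	3	2	1	1	1	1	3
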