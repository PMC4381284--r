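sirna_id	mrna_id	site_start	site_end	efficacy_code	loop5	loop3	int_loop	mb_loop	h_loop	b_loop	one_bb	stem	n_unpaired	max_run	runs	hb_index	dg_duplex	dg_break_target	dg_oligo_self	dg_overall	gc_percent
fix_sirna_1	fixA	2	20	1	1	0	2	0	4	0	1	11	8	4	1,2,1,4	30.3000	-37.5300	-30.0000	-3.0000	-4.5300	57.8947
fix_sirna_2	fixA	15	33	0	0	2	2	0	4	0	0	11	8	4	4,2,2	30.3000	-37.2400	-30.0000	-8.0000	0.7600	57.8947
fix_sirna_3	fixB	1	19	1	2	0	0	2	4	0	0	11	8	4	2,2,4	30.0000	-35.7300	-21.0000	-12.0000	-2.7300	57.8947
fix_sirna_4	fixB	18	36	0	0	0	0	5	3	0	0	11	8	3	2,3,3	30.3000	-36.6700	-21.0000	-14.0000	-1.6700	57.8947
fix_sirna_5	fixC	5	23	1	0	0	4	0	4	2	0	9	10	4	2,4,2,2	24.6000	-32.6200	-12.0000	-10.0000	-10.6200	47.3684
fix_sirna_6	fixC	14	32	0	0	0	2	0	3	3	0	11	8	3	2,3,3	32.7000	-37.4400	-21.0000	-13.0000	-3.4400	63.1579
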