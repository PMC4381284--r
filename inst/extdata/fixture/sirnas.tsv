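id	guide	target_id	efficacy
fix_sirna_1	GUUUUCCCUCCCUUCCCCU	fixA	VH
fix_sirna_2	UUGGGGUUGGGGGGUUUUC	fixA	L
fix_sirna_3	GCGCUUUUGCGCUUCCCUU	fixB	VH
fix_sirna_4	GGGUUUGGGUUUCCCUUGC	fixB	L
fix_sirna_5	UUCGCUUGGGUUUUCCCUU	fixC	VH
fix_sirna_6	GGCUUCGCUUUCGCUUGGG	fixC	L
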