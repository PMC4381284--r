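# RNA/RNA Watson-Crick nearest-neighbour stack free energies, 37 C, kcal/mol
# (Xia et al. 1998 set).  Key: top strand 5'->3' / bottom strand 3'->5'.
key	energy	source_tag
AA/UU	-0.93	xia1998-wc-37C
AC/UG	-2.24	xia1998-wc-37C
AG/UC	-2.08	xia1998-wc-37C
AU/UA	-1.10	xia1998-wc-37C
CA/GU	-2.11	xia1998-wc-37C
CC/GG	-3.26	xia1998-wc-37C
CG/GC	-2.36	xia1998-wc-37C
CU/GA	-2.08	xia1998-wc-37C
GA/CU	-2.35	xia1998-wc-37C
GC/CG	-3.42	xia1998-wc-37C
GG/CC	-3.26	xia1998-wc-37C
GU/CA	-2.24	xia1998-wc-37C
UA/AU	-1.33	xia1998-wc-37C
UC/AG	-2.35	xia1998-wc-37C
UG/AC	-2.11	xia1998-wc-37C
UU/AA	-0.93	xia1998-wc-37C
init	4.09	xia1998-wc-37C
terminal_au	0.45	xia1998-wc-37C
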