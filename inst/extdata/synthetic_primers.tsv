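mix_name	primer_name	iupac	orientation	anchor_position	coordinate_reference
DSR190f	DSR190f_v1	GGRTAYTGGAARGGHGGNTT	FORWARD	190	Desulfovibrio_vulgaris_dsrAB
DSR190f	DSR190f_v2	GGRTACTGGAAAGGYGGNTT	FORWARD	190	Desulfovibrio_vulgaris_dsrAB
DSR1762f	DSR1762f_v1	ACSCAYTGGAARCACGGNGG	FORWARD	1762	Desulfovibrio_vulgaris_dsrAB
DSR1762f	DSR1762f_v2	ACSCACTGGAAGCAYGGNGG	FORWARD	1762	Desulfovibrio_vulgaris_dsrAB
DSR2107r	DSR2107r_v1	GTRTARCAGTTDCCRCANAC	REVERSE	2107	Desulfovibrio_vulgaris_dsrAB
DSR2107r	DSR2107r_v2	GTGTAACAGTTKCCGCANAC	REVERSE	2107	Desulfovibrio_vulgaris_dsrAB
rDSR1f	rDSR1f_v1	GCYTTYATGCAYTGYCARGG	FORWARD	82	Allochromatium_vinosum_dsrAB
rDSR4r	rDSR4r_v1	CCRAARCANGCNCCRCARAT	REVERSE	2123	Allochromatium_vinosum_dsrAB
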