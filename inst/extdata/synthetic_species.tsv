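name	class	ibaq	total_copies	alpha	mw_da	predicted_diameter_nm	domains	organelle	relaxed_diameter_nm	expanded_diameter_nm
reader_1	protein	100		6	25000	3.2	O:60:1.2;D:120:?	chromatin_focus
reader_2	protein	190		4	90000	5.8	O:700:2.6;D:120:?	chromatin_focus
silencer_1	protein		60000	inf	53000	3.5	D:480:?	chromatin_focus
granule_1	protein	2400		25	33000	4.2	O:200:2.0;D:100:?	rna_body
granule_2	protein	800		20	34000	4.0	O:220:2.1;D:90:?	rna_body
assembly_1	protein		5000	inf	1500000	20		rna_body	25	33
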