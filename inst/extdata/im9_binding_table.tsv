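# Published per-orientation binding free energies (kJ/mol) for Im9
# two-bundle systems: native orientation and +30 degree rotation of the
# listed helix, with block-averaged standard errors, plus the printed
# orientation difference ddG = dG(+30) - dG(native).
system	rotated	dG_native	sem_native	dG_rot30	sem_rot30	ddG_printed
H1-H2	H1	-33	0.3	-43	1	-10
H1-H2	H2	-33	0.3	-10	0.1	23
H1-H4	H1	-28	1	-22	1	6
H1-H4	H4	-28	1	-33	1	-5
H1-NH4	H1	-44	1	-22	1	22
H1-NH4	NH4	-44	1	-21	2	23
H1-H2/H4	H1	-49	1	-71	0.1	-22
H1-H2/NH4	H1	-80	5	-78	3	2
H1-H2/H4C	H1	-55	2	-54	2	1
H1-H2/NH4C	H1	-67	4	-53	5	14
H1-H2/H3/H4	H1	-68	3	-79	1	-11
H1-H2LH3LH4C	H1	-75	1	-62	3	13
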