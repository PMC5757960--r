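# Published fragment comparisons: ddG = dG(H1, fragment B) - dG(H1,
# fragment A), per orientation (native and +30 degree H1 rotation),
# with the printed values (kJ/mol). fragment ids reference the `system`
# column of im9_binding_table.tsv (H1-<fragment>); per-orientation dG
# inputs are the rows of that table with H1 as the rotated helix.
fragment_a	fragment_b	ddG_native_printed	ddG_rot30_printed
H1-H2	H1-H2/H4	-16	-28
H1-H4	H1-H2/H4	-21	-49
H1-NH4	H1-H2/NH4	-36	-56
H1-H2/H4	H1-H2/NH4	-31	-7
H1-H2/H4	H1-H2/H4C	-6	17
H1-H2/H4	H1-H2/NH4C	-18	18
H1-H2/H4	H1-H2/H3/H4	-19	-8
H1-H2/H4	H1-H2LH3LH4C	-26	9
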