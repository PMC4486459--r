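# Peptide-contact map: mature-numbering MHC class I positions whose side
# chains are predicted to lie within 4.0 A of the bound 9-mer peptide,
# with the peptide residue(s) each position contacts. 35 positions.
# Approximate transcription: positions named in the study's text are exact;
# peptide-residue assignments for the remaining groove positions follow the
# canonical class I pocket architecture and are marked approx = yes.
mhc_pos	peptide_positions	approx
5	1	yes
7	1,2	no
9	2,9	no
24	2,9	no
33	2	yes
45	2,9	no
59	1	yes
62	1,2,3	no
63	1,2	no
66	1,2,3	no
67	2,3	no
69	3,4	yes
70	2,3,4	no
73	3,4	no
74	4,5	yes
76	8,9	yes
77	8,9	yes
80	8,9	yes
81	8,9	no
84	9	yes
95	6,9	no
97	4,5,6	no
99	3,5,9	no
113	5,6	yes
114	3,5,6	no
116	7,9	no
118	9	yes
123	7,9	yes
143	9	yes
146	8,9	yes
147	7,8,9	yes
150	6,7	yes
152	3,6,7	no
155	3,6,7	no
156	3,6,7	no
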