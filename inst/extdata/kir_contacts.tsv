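# MHC class I positions (mature numbering) contacting the KIR D1/D2
# domains at the C-terminal end of the peptide-binding groove; 14
# positions, of which five are critical for KIR3DL1 affinity in
# mutational studies. Approximate transcription: the critical five are
# exact, the remainder follow the canonical KIR3DL1 footprint.
mhc_pos	critical
76	no
79	no
80	yes
82	no
83	yes
84	no
88	no
89	no
142	yes
145	no
146	yes
149	yes
150	no
151	no
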