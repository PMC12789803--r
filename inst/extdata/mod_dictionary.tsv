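comp_id	canonical	display_char	mod_class	gly_atom1	gly_atom2
PSU	U	P	BASE	C5	C4
5MU	U	t	BASE	N1	C2
UR3	U	u	BASE	N1	C2
OMU	U	u	SUGAR	N1	C2
4SU	U	u	BASE	N1	C2
H2U	U	u	BASE	N1	C2
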