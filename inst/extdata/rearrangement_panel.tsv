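id	operation	locus_a	locus_b	locus_target	type_a	type_b	type_target	strand_a	strand_b	strand_target	expected_inverted_repeat	expected_cre_independent	description
R01	deletion	A	lacZ	NA	Ll.LtrB	Ll.LtrB	NA	s	s	NA	no	yes	A-lacZ deletion, homologous introns in direct orientation
R02	deletion	A	lacZ	NA	Ll.LtrB	EcI5	NA	s	s	NA	no	no	A-lacZ deletion, non-homologous introns
R03	deletion	B	C	NA	EcI5	EcI5	NA	s	a	NA	yes	no	B-C deletion, homologous introns in inverted orientation
R04	deletion	D	E	NA	EcI5	EcI5	NA	s	a	NA	yes	no	D-E deletion, homologous introns in inverted orientation
R05	inversion	A	lacZ	NA	EcI5	EcI5	NA	s	s	NA	yes	no	A-lacZ inversion, homologous introns in direct orientation
R06	inversion	A	lacZ	NA	EcI5	Ll.LtrB	NA	s	s	NA	no	no	A-lacZ inversion, non-homologous introns
R07	inversion	B	lacZ	NA	EcI5	EcI5	NA	s	s	NA	yes	no	B-lacZ inversion, homologous introns in direct orientation
R08	inversion	E	lacZ	NA	EcI5	EcI5	NA	s	a	NA	no	yes	E-lacZ inversion, homologous introns in inverted orientation (reversible)
R09	inversion	E	lacZ	NA	EcI5	Ll.LtrB	NA	s	s	NA	no	no	E-lacZ inversion, non-homologous introns
R10	inversion	D	E	NA	EcI5	EcI5	NA	s	a	NA	no	yes	D-E inversion, homologous introns in inverted orientation (reversible)
R11	cut_and_paste	A	lacZ	E	Ll.LtrB	EcI5	EcI5	s	s	a	yes	some	A-lacZ region translocated to E, homologous introns at lacZ and E in inverted orientation
R12	cut_and_paste	D	E	B	Ll.LtrB	EcI5	EcI5	s	s	a	yes	some	D-E region translocated to B, homologous introns at E and B in inverted orientation
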