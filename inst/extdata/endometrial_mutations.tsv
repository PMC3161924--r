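case	subtype	c_change	aa_change	type
T3	NEEC	c.G905T	S302I	Missense
T3	NEEC	c.C1169A	A390D	Missense
T3	NEEC	c.G2167T	E723X	Nonsense
T3	NEEC	c.G4380A	E1460E	Synonymous
T113	NEEC	c.G892A	E298K	Missense
T113	NEEC	c.G1913T	S638I	Missense
T113	NEEC	c.C4546A	P1516T	Missense
T113	NEEC	c.C4143A	D1381E	Missense
T51	NEEC	c.C4240T	R1414X	Nonsense
T62	NEEC	c.C4766G	S1589C	Missense
T88	EEC	c.C272A	P91H	Missense
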