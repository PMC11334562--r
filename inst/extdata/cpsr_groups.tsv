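scheme	residue	class
exchange	H	e1
exchange	R	e1
exchange	K	e1
exchange	D	e2
exchange	E	e2
exchange	N	e2
exchange	Q	e2
exchange	C	e3
exchange	S	e4
exchange	T	e4
exchange	P	e4
exchange	A	e4
exchange	G	e4
exchange	M	e5
exchange	I	e5
exchange	L	e5
exchange	V	e5
exchange	F	e6
exchange	Y	e6
exchange	W	e6
electron	D	donor
electron	E	donor
electron	P	donor
electron	A	donor
electron	V	weak_donor
electron	L	weak_donor
electron	I	weak_donor
electron	K	acceptor
electron	N	acceptor
electron	R	acceptor
electron	F	weak_acceptor
electron	Y	weak_acceptor
electron	M	weak_acceptor
electron	T	weak_acceptor
electron	Q	weak_acceptor
electron	G	neutral
electron	H	neutral
electron	W	neutral
electron	S	neutral
electron	C	special
r_group	G	nonpolar_aliphatic
r_group	A	nonpolar_aliphatic
r_group	V	nonpolar_aliphatic
r_group	L	nonpolar_aliphatic
r_group	I	nonpolar_aliphatic
r_group	M	nonpolar_aliphatic
r_group	P	nonpolar_aliphatic
r_group	F	aromatic
r_group	Y	aromatic
r_group	W	aromatic
r_group	S	polar_uncharged
r_group	T	polar_uncharged
r_group	C	polar_uncharged
r_group	N	polar_uncharged
r_group	Q	polar_uncharged
r_group	K	positive
r_group	R	positive
r_group	H	positive
r_group	D	negative
r_group	E	negative
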