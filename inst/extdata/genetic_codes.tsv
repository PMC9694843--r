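table_id	codon	aa
1	AAA	K
1	AAC	N
1	AAG	K
1	AAT	N
1	ACA	T
1	ACC	T
1	ACG	T
1	ACT	T
1	AGA	R
1	AGC	S
1	AGG	R
1	AGT	S
1	ATA	I
1	ATC	I
1	ATG	M
1	ATT	I
1	CAA	Q
1	CAC	H
1	CAG	Q
1	CAT	H
1	CCA	P
1	CCC	P
1	CCG	P
1	CCT	P
1	CGA	R
1	CGC	R
1	CGG	R
1	CGT	R
1	CTA	L
1	CTC	L
1	CTG	L
1	CTT	L
1	GAA	E
1	GAC	D
1	GAG	E
1	GAT	D
1	GCA	A
1	GCC	A
1	GCG	A
1	GCT	A
1	GGA	G
1	GGC	G
1	GGG	G
1	GGT	G
1	GTA	V
1	GTC	V
1	GTG	V
1	GTT	V
1	TAC	Y
1	TAT	Y
1	TCA	S
1	TCC	S
1	TCG	S
1	TCT	S
1	TGC	C
1	TGG	W
1	TGT	C
1	TTA	L
1	TTC	F
1	TTG	L
1	TTT	F
1	TAA	*
1	TAG	*
1	TGA	*
2	AAA	K
2	AAC	N
2	AAG	K
2	AAT	N
2	ACA	T
2	ACC	T
2	ACG	T
2	ACT	T
2	AGC	S
2	AGT	S
2	ATA	M
2	ATC	I
2	ATG	M
2	ATT	I
2	CAA	Q
2	CAC	H
2	CAG	Q
2	CAT	H
2	CCA	P
2	CCC	P
2	CCG	P
2	CCT	P
2	CGA	R
2	CGC	R
2	CGG	R
2	CGT	R
2	CTA	L
2	CTC	L
2	CTG	L
2	CTT	L
2	GAA	E
2	GAC	D
2	GAG	E
2	GAT	D
2	GCA	A
2	GCC	A
2	GCG	A
2	GCT	A
2	GGA	G
2	GGC	G
2	GGG	G
2	GGT	G
2	GTA	V
2	GTC	V
2	GTG	V
2	GTT	V
2	TAC	Y
2	TAT	Y
2	TCA	S
2	TCC	S
2	TCG	S
2	TCT	S
2	TGA	W
2	TGC	C
2	TGG	W
2	TGT	C
2	TTA	L
2	TTC	F
2	TTG	L
2	TTT	F
2	AGA	*
2	AGG	*
2	TAA	*
2	TAG	*
5	AAA	K
5	AAC	N
5	AAG	K
5	AAT	N
5	ACA	T
5	ACC	T
5	ACG	T
5	ACT	T
5	AGA	S
5	AGC	S
5	AGG	S
5	AGT	S
5	ATA	M
5	ATC	I
5	ATG	M
5	ATT	I
5	CAA	Q
5	CAC	H
5	CAG	Q
5	CAT	H
5	CCA	P
5	CCC	P
5	CCG	P
5	CCT	P
5	CGA	R
5	CGC	R
5	CGG	R
5	CGT	R
5	CTA	L
5	CTC	L
5	CTG	L
5	CTT	L
5	GAA	E
5	GAC	D
5	GAG	E
5	GAT	D
5	GCA	A
5	GCC	A
5	GCG	A
5	GCT	A
5	GGA	G
5	GGC	G
5	GGG	G
5	GGT	G
5	GTA	V
5	GTC	V
5	GTG	V
5	GTT	V
5	TAC	Y
5	TAT	Y
5	TCA	S
5	TCC	S
5	TCG	S
5	TCT	S
5	TGA	W
5	TGC	C
5	TGG	W
5	TGT	C
5	TTA	L
5	TTC	F
5	TTG	L
5	TTT	F
5	TAA	*
5	TAG	*
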