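mirna	target	reference
mir-192	MDM2	curated
mir-192	EGFR	curated
mir-192	PIK3CA	curated
mir-192	TP53	curated
mir-192	PTEN	curated
mir-192	CDKN1	curated
mir-181c	AKT	curated
mir-181c	MYC	curated
mir-489	CDKN1	curated
mir-489	PIK3CA	curated
mir-489	TP53	curated
mir-489	AKT	curated
mir-34a	MTOR	curated
mir-34a	ERK	curated
mir-34a	MDM2	curated
mir-34a	PIK3R1	curated
mir-34a	EGFR	curated
mir-34a	RPS6KA5	curated
mir-34a	CAMK	curated
mir-34a	TP53	curated
mir-34a	PTEN	curated
mir-34a	PKC	curated
mir-34a	PDPK1	curated
mir-34a	MYC	curated
mir-34a	CDKN1	curated
mir-34a	ELK1	curated
mir-TRDD	TARBP2	curated
mir-TRDD	RNASEN	curated
mir-TRDD	DICER1	curated
mir-TRDD	DGCR8	curated
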