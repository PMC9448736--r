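kinase	accession	position	residue
KIN001	PROT00006	638	T
KIN001	PROT00002	157	T
KIN001	PROT00020	903	S
KIN001	PROT00003	78	S
KIN002	PROT00002	157	T
KIN002	PROT00010	28	S
KIN002	PROT00005	150	S
KIN002	PROT00017	414	T
KIN003	PROT00013	605	S
KIN004	PROT00012	360	S
KIN004	PROT00009	307	S
KIN004	PROT00020	903	S
KIN005	PROT00010	28	S
KIN005	PROT00014	169	S
KIN005	PROT00002	157	T
KIN005	PROT00017	414	T
KIN005	PROT00005	150	S
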