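gene	log2fc	pvalue	comparison_id
KIN001	3.18198548609592	0.00570466212035247	treated_vs_control
KIN002	0.229522200292006	0.0836952936369926	treated_vs_control
KIN003	-0.466310389205213	0.0486410746816546	treated_vs_control
KIN004	-0.0129706542618338	0.979815867030993	treated_vs_control
KIN005	0.265049866061373	0.484167741145939	treated_vs_control
GENE0001	-0.43751579609008	0.845393033931032	treated_vs_control
GENE0002	-0.123816194758946	0.416293604532257	treated_vs_control
GENE0003	0.0106484173891873	0.489342542830855	treated_vs_control
GENE0004	0.0343008596608975	0.183287817519158	treated_vs_control
GENE0005	-0.413821727973915	0.759161467896774	treated_vs_control
GENE0006	-0.640003717470602	0.305143302539364	treated_vs_control
GENE0007	-0.224652730389712	0.165678247110918	treated_vs_control
GENE0008	-0.0128449709724735	0.0328091429546475	treated_vs_control
GENE0009	0.424221923600606	0.13650520821102	treated_vs_control
GENE0010	0.317614217890869	0.177136411424726	treated_vs_control
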