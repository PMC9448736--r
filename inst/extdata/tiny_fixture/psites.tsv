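accession	position	residue	lp_class	control:1	control:2	treated:1	treated:2
PROT00001	325	Y	I	7448422.23300928	7017023.87293059		4509952.56990079
PROT00002	157	T	III	2777581.76887883	2286553.54638237	11922261.4495507	12135942.0018788
PROT00003	78	S	I	45154.3584529485	50917.1364489022	394489.388272881	633965.417611514
PROT00004	232	S	II	2380525.95747375	3247657.85058724	2078769.82887519	3251102.951388
PROT00005	150	S	II	830519.700687821	669355.723131855	524361.832747207	674573.022864981
PROT00006	638	T	I	1327595.18215019	733459.598397032	10887586.053532	
PROT00007	53	S	III	430129.714104902		915258.308569311	649885.029563415
PROT00008	132	S	I	2906741.29914897	3016786.61692258		2376524.7754974
PROT00009	307	S	I		806391.884603358	829230.167851536	528672.273697462
PROT00010	28	S	I	1013709.24805285	1210152.87126817	1026666.68517959	2127043.31338557
PROT00011	843	S	I	609177.567375562	738857.566989527	757542.291155527	604145.993152078
PROT00012	360	S	I	5271611.1631894	5880631.82002734	4580300.05513344	3528642.34711763
PROT00013	605	S	I	1452327.06908126	1545240.81881063	2680862.07464547	1132937.83124733
PROT00014	169	S	I	1229572.73473815	1431318.49371821	1042299.75414187	
PROT00015	626	S	I	4576109.91387065	3147097.68380934	4723160.55696174	4310482.24712011
PROT00016	536	S	I	929953.498087853	1566390.35695585	1507926.69717801	874506.492165436
PROT00017	414	T	I	317074.754417471		306663.133457478	319267.092216605
PROT00018	886	S	I	1646910.2581938	1868739.23804395	1477966.30329199	863924.85500315
PROT00019	883	S	I	322955.045868018	193935.690507679	183974.898878821	237368.07772728
PROT00020	903	S	III	1837956.54299685		25808939.6725398	15452951.5393021
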