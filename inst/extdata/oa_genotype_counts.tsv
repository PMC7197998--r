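snp_id	gene	group	n0	n1	n2
rs3025039	VEGFA	case	31	37	12
rs3025039	VEGFA	control	57	44	18
rs699947	VEGFA	case	39	34	8
rs699947	VEGFA	control	57	41	16
rs11292	HIF1AN	case	61	0	14
rs11292	HIF1AN	control	51	25	11
rs1800255	COL3A1	case	35	42	7
rs1800255	COL3A1	control	30	39	5
rs4444903	EGF	case	23	41	18
rs4444903	EGF	control	31	56	24
rs679620	MMP3	case	39	30	11
rs679620	MMP3	control	41	27	11
rs2252070	MMP13	case	38	41	6
rs2252070	MMP13	control	46	41	7
rs2297518	NOS2	case	65	14	1
rs2297518	NOS2	control	66	15	1
rs2070744	NOS3	case	58	23	6
rs2070744	NOS3	control	53	24	7
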