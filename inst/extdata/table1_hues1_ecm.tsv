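gene_symbol	protein_name	CD1_P4	CD1_P9	MF1xCD1_P4	MF1xCD1_P9	hPSF	ihPSF	HUES1	not_in_HUES1
ADAMTS4	ADAM-TS4		0.500			1.18	2.03	4.76	FALSE
AGRN	Agrin							10.0	FALSE
APOE	Apolipoprotein E							215	FALSE
CLU	Clusterin							43.1	FALSE
COL12A1	Collagen, type XII, alpha 1	2.60	1.91	8.23	6.44		0.470		TRUE
COL18A1	Collagen, type XVIII, alpha 1							5.83	FALSE
COL1A1	Collagen, type I, alpha 1		1.14	1.45	3.70	1.02	7.36	54.3	FALSE
COL1A2	Collagen, type I, alpha 2	0.439	0.520	1.34	3.26		3.06	18.1	FALSE
COL2A1	Collagen, type II, alpha 1							1.2	FALSE
COL3A1	Collagen, type III, alpha 1		0.490						TRUE
COL4A1	Collagen, type IV, alpha 1			0.253			1.63	5.52	FALSE
COL4A2	Collagen, type IV, alpha 2			0.184			1.04	18.5	FALSE
COL5A1	Collagen, type V, alpha 1			0.330					TRUE
COL5A2	Collagen, type V, alpha 2			0.640					TRUE
COL6A1	Collagen, type VI, alpha 1			0.800	1.46	0.740	5.23		TRUE
COL6A2	Collagen, type VI, alpha 2				0.960	0.980	4.49		TRUE
COL6A3	Collagen, type VI, alpha 3					1.25	8.41		TRUE
CYR61	CYR61	1.58	2.68	0.732		21.5	47.0	2.55	FALSE
EGFL7	EGF-like protein 7							12.5	FALSE
EMID2	Collagen, type XXVI, alpha 1							8.34	FALSE
EMILIN1	EMILIN-1	13.7	27.3	13.0	34.7	24.9	49.7	13.2	FALSE
EMILIN2	EMILIN-2				1.25			1.39	FALSE
FBLN2	Fibulin-2	54.4	31.8	32.8	69.6			6.13	FALSE
FBN1	Fibrillin-1	0.274		0.262	10.1		0.375	3.09	FALSE
FBN2	Fibrillin-2				0.671			11.0	FALSE
FGFBP3	FGF-binding protein 3							5.74	FALSE
FN1	Fibronectin-1	99.1	117	95.1	118	2.34	57.2	81.9	FALSE
HNRNPM	hnRNP M		1.00					15.9	FALSE
HSP90B1	Endoplasmin					1.00	1.19	4.08	FALSE
HSPG2	Perlecan	6.63	13.1	10.3	15.8		4.16	15.7	FALSE
KRT1	Keratin, type II, cytoskeletal 1	8.78	12.9	6.65	11.6	107	70.5	13.9	FALSE
LAMA1	Laminin alpha 1							1.97	FALSE
LAMA5	Laminin alpha 5						0.219	1.82	FALSE
LAMB1	Laminin beta 1						0.295	5.29	FALSE
LAMC1	Laminin gamma 1						0.329	10.8	FALSE
LEFTY2	TGF-beta 4							16.7	FALSE
NID1	Nidogen-1			1.08			0.645	2.59	FALSE
NID2	Nidogen-2	0.370	0.731		15.5			1.07	FALSE
PKM2	Pyruvate kinase isozyme M1			0.796			1.76	4.62	FALSE
THBS1	Thrombospondin-1	13.9	29.0	20.8	7.84	1.79	4.93	1.25	FALSE
TNC	Tenascin C	1.17	3.21	2.91	4.58	12.3	17.2	4.23	FALSE
VCAN	Versican					0.937	1.71	3.44	FALSE
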