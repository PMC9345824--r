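trait_pair	snp	chr	bp	a1	a2	eaf	beta_pcos	beta_trait	p_pcos	p_trait	p_cpassoc	novel	genes
T2DM	rs8050136	16	53816275	A	C	0.41	0.15	0.12	4.50e-6	7.60e-74	1.95e-85	FALSE	FTO
T2DM	rs9675376	18	57969244	A	G	0.30	0.13	0.04	2.40e-4	3.90e-9	4.47e-10	FALSE	NA
T2DM	rs72753599	1	214180519	T	C	0.20	-0.14	-0.06	6.00e-4	1.60e-12	3.94e-13	FALSE	PROX1
T2DM	rs10938398	4	45186139	A	G	0.42	0.11	0.04	8.80e-4	4.90e-12	1.02e-12	FALSE	NA
T2DM_adj_BMI	rs9930501	16	53830452	A	G	0.55	-0.14	-0.05	5.30e-6	6.00e-13	6.07e-15	FALSE	FTO
T2DM_adj_BMI	rs1509097	2	165737931	T	C	0.50	-0.13	-0.04	5.20e-5	5.30e-7	3.34e-8	TRUE	SLC38A11
T2DM_adj_BMI	rs2238689	19	46178661	T	C	0.57	0.11	-0.07	5.40e-4	1.40e-21	9.67e-24	FALSE	EML2,FBXO46,GIPR,MIR642A,MIR642B,QPCTL,SNRPD2
T2DM_adj_BMI	rs72753599	1	214180519	T	C	0.20	-0.14	-0.07	6.00e-4	1.60e-12	6.26e-14	FALSE	PROX1
T2DM_adj_BMI	rs3934729	3	123019763	T	C	0.61	-0.11	0.04	7.40e-4	1.60e-7	1.44e-8	TRUE	ADCY5,SEC22A
FG_adj_BMI	rs72753599	1	214180519	T	C	0.20	-0.14	-0.01	6.00e-4	5.06e-12	1.62e-12	FALSE	PROX1
FG_adj_BMI	rs9844212	3	123021870	C	G	0.59	-0.11	0.01	6.00e-4	7.35e-13	4.41e-13	FALSE	ADCY5,SEC22A
FG_adj_BMI	rs6485690	11	46798631	A	G	0.34	-0.11	0.01	9.40e-4	4.60e-9	1.06e-10	FALSE	ARFGAP2,ARHGAP1,ATG13,CSTPP1,CKAP5,DDB2,F2,LRP4,LRP4-AS1,MIR5582,MIR6745,PACSIN3,SNORD67,ZNF408
FI_adj_BMI	rs745379	8	11615695	A	G	0.48	-0.12	-0.01	3.40e-4	8.26e-6	1.49e-9	TRUE	LINC02905,FDFT1,GATA4,LINC00208,NEIL2
FI_adj_BMI	rs3813583	16	79755080	A	C	0.62	0.12	0.01	4.80e-4	1.88e-4	2.64e-8	TRUE	NA
FI_adj_BMI	rs4135247	3	12396588	A	G	0.56	-0.11	-0.01	6.00e-4	1.49e-6	6.02e-9	TRUE	PPARG
HbA1c	rs8047587	16	53798622	T	G	0.45	0.14	0.01	6.80e-6	1.87e-5	2.87e-10	TRUE	FTO
HbA1c	rs1265564	12	111708458	A	C	0.58	0.13	0.01	1.60e-4	5.62e-12	2.91e-13	FALSE	ACAD10,ATXN2,BRAP,CUX2,PHETA1,MIR6760,SH2B3
HbA1c	rs2238689	19	46178661	T	C	0.57	0.11	-0.01	5.40e-4	1.45e-6	1.12e-8	TRUE	GIPR,MIR642A,MIR642B
HbA1c	rs4731113	7	123283949	T	C	0.97	0.31	0.02	8.00e-4	4.90e-8	3.28e-9	FALSE	LMOD2,WASL
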