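gene	putative_function	category	log2fc	q
Solyc05g013220	Ketoacyl-CoA synthase KCS	Wax Biosynthesis	-1.97	5.0E-62
Solyc06g074390	Fatty acyl-CoA reductase FAR1	Wax Biosynthesis	1.24	3.5E-17
Solyc03g117800	ECERIFERUM 3 CER3	Wax Biosynthesis	-1.28	6.4E-58
Solyc10g080840	Cytochrome P450 MAH1	Wax Biosynthesis	-1.86	8.6E-209
Solyc08g081220	Cytochrome P450 CYP86A69 CD3	Cutin Biosynthesis	-2.20	1.3E-254
Solyc04g082380	Cytochrome P450 CYP86A8-like	Cutin Biosynthesis	-1.10	4.4E-08
Solyc09g014350	Glycerol-3-phosphate acyltransferase GPAT6	Cutin Biosynthesis	-1.20	8.9E-69
Solyc10g075100	Non-specific lipid-transfer protein LTP2_1e	Lipid Transport	2.98	0.0E+00
Solyc09g018010	Non-specific lipid-transfer protein LTP2_2	Lipid Transport	1.37	6.9E-16
Solyc10g075110	Non-specific lipid-transfer protein LTP2_1f	Lipid Transport	2.50	8.4E-31
Solyc08g067540	Non-specific lipid-transfer protein	Lipid Transport	1.57	3.4E-07
Solyc05g015490	Plant lipid transfer protein LTPG1	Lipid Transport	-3.37	7.0E-88
Solyc02g071610	GDSL esterase/lipase	Polymerization	1.58	7.3E-93
Solyc02g071700	GDSL esterase/lipase	Polymerization	2.41	2.1E-50
Solyc07g049440	GDSL esterase/lipase	Polymerization	-1.88	0.0E+00
Solyc03g121180	GDSL esterase/lipase	Polymerization	1.08	6.8E-74
Solyc10g076740	GDSL esterase/lipase CPRD49	Polymerization	-1.10	8.9E-29
Solyc11g006250	GDSL esterase/lipase CUS1	Polymerization	1.22	1.4E-69
Solyc06g083650	GDSL esterase/lipase CUS4	Polymerization	-1.12	1.1E-33
Solyc08g008610	Alpha/beta-Hydrolases superfamily protein BDG1	Polymerization	3.53	7.1E-151
Solyc02g088190	SlMIXTA-like	Regulation	-1.08	1.0E-59
Solyc05g056170	Phenylalanine ammonia-lyase	Phenylpropanoid Pathway	-1.84	1.6E-122
Solyc09g007890	Phenylalanine ammonia-lyase	Phenylpropanoid Pathway	1.17	4.8E-87
Solyc10g086180	Phenylalanine ammonia-lyase	Phenylpropanoid Pathway	1.57	3.3E-42
Solyc09g007910	Phenylalanine ammonia-lyase	Phenylpropanoid Pathway	2.47	2.8E-202
Solyc00g500353	Phenylalanine ammonia-lyase	Phenylpropanoid Pathway	4.59	0.0E+00
Solyc09g007920	Phenylalanine ammonia-lyase	Phenylpropanoid Pathway	1.08	7.8E-84
Solyc02g093230	Caffeoyl-CoA O-methyltransferase	Phenylpropanoid Pathway	1.78	9.9E-34
Solyc02g093250	Caffeoyl-CoA O-methyltransferase	Phenylpropanoid Pathway	1.79	2.9E-50
Solyc09g091510	Chalcone synthase 1 CHS1	Phenylpropanoid Pathway	1.91	6.6E-121
Solyc01g111070	Chalcone synthase-like	Phenylpropanoid Pathway	1.32	3.6E-30
Solyc12g015770	Cellulose synthase	Cell Wall	-2.00	3.7E-83
Solyc07g043390	Cellulose synthase	Cell Wall	1.67	5.3E-41
Solyc03g097050	Cellulose synthase	Cell Wall	3.96	0.0E+00
Solyc02g089640	Cellulose-synthase-like C4	Cell Wall	1.71	1.8E-189
Solyc01g065530	COBRA-like protein	Cell Wall	1.92	2.2E-221
Solyc08g081620	Endo-1,4-beta-glucanase precursor	Cell Wall	-1.05	1.9E-07
Solyc08g082250	Endo-beta-1,4-D-glucanase Cel8	Cell Wall	1.01	7.5E-88
Solyc07g049300	Endoglucanase	Cell Wall	1.18	1.5E-61
Solyc07g064870	Endoglucanase	Cell Wall	1.59	5.1E-71
Solyc03g071570	Pectate lyase	Cell Wall	1.29	3.0E-60
Solyc09g091430	Pectate lyase	Cell Wall	1.90	9.2E-102
Solyc09g061890	Pectate lyase	Cell Wall	2.26	5.4E-231
Solyc04g082140	Pectinesterase	Cell Wall	1.31	4.6E-116
Solyc06g009190	Pectinesterase	Cell Wall	1.20	7.4E-36
Solyc03g123620	Pectinesterase	Cell Wall	2.71	0.0E+00
Solyc03g083730	Plant invertase/pectin methylesterase inhibitor	Cell Wall	1.65	2.8E-12
Solyc12g010540	UDP-glucuronate 4-epimerase 4	Cell Wall	1.70	3.9E-135
Solyc05g051260	1,4-beta-xylanase	Cell Wall	2.40	8.5E-07
Solyc03g093080	Xyloglucan endotransglucosylase/hydrolase	Cell Wall	3.50	0.0E+00
Solyc07g055990	Xyloglucan endotransglucosylase/hydrolase	Cell Wall	4.05	4.4E-208
Solyc02g080160	Xyloglucan endotransglucosylase/hydrolase	Cell Wall	1.62	3.6E-101
Solyc07g056000	Xyloglucan endotransglucosylase/hydrolase	Cell Wall	3.09	0.0E+00
Solyc03g093110	Xyloglucan endotransglucosylase/hydrolase	Cell Wall	3.96	0.0E+00
Solyc07g009380	Xyloglucan endotransglucosylase-hydrolase 2	Cell Wall	-1.14	3.0E-86
Solyc03g093130	Xyloglucan endotransglucosylase-hydrolase 3	Cell Wall	4.19	0.0E+00
Solyc12g011030	Xyloglucan endotransglucosylase-hydrolase 9	Cell Wall	3.02	5.7E-234
Solyc12g017240	Xyloglucan endo-transglycosylase B1	Cell Wall	2.73	0.0E+00
Solyc07g044960	Xyloglucan galactosyltransferase KATAMARI1	Cell Wall	3.89	6.7E-72
Solyc03g093120	Xyloglucan:xyloglucosyl transferase TCH4	Cell Wall	4.87	0.0E+00
Solyc06g074670	UDP-apiose/UDP-xylose synthase	Cell Wall	2.57	0.0E+00
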