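gene	putative_function	category	log2fc	q
Solyc12g006460	GA ent-kaurenoate oxidase	Gibberellin	4.26	2.5E-249
Solyc07g056670	Gibberellin 2-oxidase	Gibberellin	-3.52	4.2E-46
Solyc09g074270	Gibberellin receptor	Gibberellin	2.34	1.1E-87
Solyc04g017720	Gibberellin regulated protein GASA6	Gibberellin	-2.04	2.3E-17
Solyc04g078195	Gibberellin-regulated protein	Gibberellin	1.12	5.0E-84
Solyc07g049550	1-aminocyclopropane-1-carboxylate oxidase 2 ACO2	Ethylene synthesis and signalling	-3.35	3.8E-26
Solyc07g026650	1-aminocyclopropane-1-carboxylate oxidase 5 ACO5	Ethylene synthesis and signalling	-1.47	2.3E-13
Solyc02g091990	Aminocyclopropane-1-carboxylate synthase 3 ACS3	Ethylene synthesis and signalling	3.48	1.4E-74
Solyc09g089610	Ethylene receptor-like protein ETR6	Ethylene synthesis and signalling	-1.81	5.3E-38
Solyc10g006130	EAR motif SlERF36	Ethylene response	1.30	3.1E-135
Solyc05g052030	Ethylene response factor 4	Ethylene response	-3.90	8.6E-42
Solyc03g093610	Ethylene response factor A.2	Ethylene response	2.42	3.0E-144
Solyc04g014530	Ethylene response factor C.2	Ethylene response	-1.08	7.0E-14
Solyc02g077370	Ethylene response factor C.5	Ethylene response	1.74	2.1E-29
Solyc03g093560	Ethylene response factor C.6	Ethylene response	2.32	2.5E-35
Solyc01g108240	Ethylene response factor D.3	Ethylene response	3.96	0.0E+00
Solyc10g050970	Ethylene response factor D.4	Ethylene response	4.26	0.0E+00
Solyc07g053740	Ethylene response factor F.4	Ethylene response	1.29	2.1E-20
Solyc05g051200	Ethylene-responsive factor 1	Ethylene response	-2.02	6.8E-31
Solyc04g011440	Ethylene-responsive heat shock protein cognate 70	Ethylene response	2.44	0.0E+00
Solyc02g070040	Ethylene-responsive nuclear protein ERT2	Ethylene response	4.10	3.8E-135
Solyc08g080630	Ethylene-responsive proteinase inhibitor 1	Ethylene response	-7.90	4.6E-25
Solyc12g056980	Ethylene-responsive transcription factor	Ethylene response	-1.18	4.6E-15
Solyc11g012980	Ethylene-responsive transcription factor	Ethylene response	1.52	1.2E-62
Solyc06g035700	Ethylene-responsive transcription factor	Ethylene response	3.60	5.2E-59
Solyc11g042560	Ethylene-responsive transcription factor	Ethylene response	5.27	3.6E-56
Solyc08g082210	Ethylene-responsive transcription factor	Ethylene response	-1.43	2.3E-43
Solyc12g009240	Ethylene-responsive transcription factor	Ethylene response	1.26	3.2E-107
Solyc01g090560	Ethylene-responsive transcription factor	Ethylene response	1.60	3.3E-30
Solyc01g090340	Ethylene-responsive transcription factor 2	Ethylene response	3.88	3.5E-77
Solyc02g077840	Ethylene-responsive transcription factor 4	Ethylene response	1.17	1.1E-18
Solyc08g078190	Ethylene-responsive transcription factor 5	Ethylene response	1.15	1.7E-32
Solyc03g093550	Ethylene-responsive transcription factor 5	Ethylene response	1.62	4.6E-72
Solyc03g093540	Ethylene-responsive transcription factor 5	Ethylene response	2.28	6.1E-12
Solyc04g078640	Ethylene-responsive transcription factor RAP2-1	Ethylene response	-1.85	8.0E-11
Solyc06g062920	Auxin-regulated dual specificity cytosolic kinase	Auxin synthesis, transport and response	2.57	4.1E-236
Solyc03g120380	Auxin-regulated IAA19	Auxin synthesis, transport and response	1.51	2.0E-37
Solyc06g008580	Auxin-regulated IAA22	Auxin synthesis, transport and response	1.69	2.4E-22
Solyc08g021820	Auxin-regulated IAA29	Auxin synthesis, transport and response	-2.31	5.2E-31
Solyc12g096570	Auxin-regulated organ size gene	Auxin synthesis, transport and response	-4.27	1.6E-31
Solyc06g075690	Auxin-regulated protein AF416289	Auxin synthesis, transport and response	4.87	5.5E-203
Solyc04g053010	Auxin-responsive protein SAUR65	Auxin synthesis, transport and response	1.56	3.4E-74
Solyc01g099840	Dormancy/auxin associated protein	Auxin synthesis, transport and response	-1.15	1.3E-44
Solyc10g079640	IAA-amino acid hydrolase ILR1-like 6	Auxin synthesis, transport and response	1.74	2.1E-76
Solyc06g059730	PIN6	Auxin synthesis, transport and response	6.11	3.3E-51
Solyc01g110920	Small auxin up-regulated RNA26	Auxin synthesis, transport and response	-1.06	2.0E-18
Solyc04g081250	Small auxin up-regulated RNA51	Auxin synthesis, transport and response	-1.39	2.4E-17
Solyc04g081270	Small auxin up-regulated RNA52	Auxin synthesis, transport and response	-1.93	8.6E-24
Solyc02g084850	Abscisic acid environmental stress-inducible protein TAS14	Abscisic Acid	1.13	3.8E-08
Solyc03g095780	Abscisic acid receptor PYL4-like	Abscisic Acid	1.99	3.7E-48
Solyc08g005610	Cytochrome P450 CYP707A ABA	Abscisic Acid	3.18	4.3E-26
Solyc02g071990	Brassinosteroid signaling positive regulator-related protein BES1/BZR1	Brassinosteroid	1.20	1.9E-55
Solyc07g062260	Brassinosteroid signaling positive regulator-related protein BES1/BZR1	Brassinosteroid	1.55	6.4E-34
Solyc11g069570	Cytokinin riboside 5'-monophosphate phosphoribohydrolase	Cytokinin	1.26	8.0E-12
Solyc09g061840	3-ketoacyl-CoA thiolase peroxisomal-like	Jasmonate	1.02	2.8E-26
Solyc07g006890	Cytochrome P450 CYP94B jasmonate	Jasmonate	3.01	0.0E+00
Solyc12g009220	Jasmonate ZIM-domain protein 1	Jasmonate	6.33	2.1E-139
Solyc07g042170	Jasmonate ZIM-domain protein 3	Jasmonate	1.82	3.9E-187
Solyc08g076930	Jasmonic acid 3	Jasmonate	1.11	3.2E-76
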