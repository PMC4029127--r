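family	conservation	n_species	seedlings	flag_leaves	seed_5d	seed_10d	seed_20d	total	log2fc_flag_leaves	log2fc_seed_5d	log2fc_seed_10d	log2fc_seed_20d
miR156	highly_conserved	2	15055	36735	1193	4048	4804	61835	1.3	-3.7	-1.9	-1.6
miR159	highly_conserved	1	17	82	13	4	11	127	2.3	-0.4	-2.1	-0.6
miR160	highly_conserved	1	1	2	1	0	8	12	1.0	0.0	-	3.0
miR164	highly_conserved	1	206	145	135	246	244	976	-0.5	-0.6	0.3	0.2
miR166	highly_conserved	2	2345	2782	4556	1239	2350	13272	0.2	1.0	-0.9	0.0
miR167	highly_conserved	3	3678	9319	1130	2213	4623	20963	1.3	-1.7	-0.7	0.3
miR168	highly_conserved	2	56845	134020	15007	18239	14070	238182	1.2	-1.9	-1.6	-2.0
miR169	highly_conserved	1	24	1	87	68	19	199	-4.6	1.9	1.5	-0.3
miR171	highly_conserved	1	26	17	18	9	7	77	-0.6	-0.5	-1.5	-1.9
miR172	highly_conserved	2	422	2273	47	89	102	2933	2.4	-3.2	-2.2	-2.0
miR395	highly_conserved	1	5	0	0	0	0	5	-	-	-	-
miR396	highly_conserved	4	303	422	91	65	40	921	0.5	-1.7	-2.2	-2.9
miR398	highly_conserved	1	1	15	0	0	0	16	3.9	-	-	-
miR1122	moderately_conserved	1	1	1	0	0	0	2	0.0	-	-	-
miR1318	moderately_conserved	1	10	366	1	1	1	379	5.2	-3.3	-3.3	-3.3
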