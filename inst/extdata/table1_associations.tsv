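habitat	layer	partition	neg	pos	pro_printed
Agricultural field	Whole	all	164,927	259,619	0.388
Agricultural field	Whole	bacterial	138,192	212,108	0.394
Agricultural field	Whole	fungal	109	10,822	0.010
Agricultural field	Whole	bacterial_fungal	26,626	36,689	0.421
Forest	Whole	all	49,985	94,015	0.347
Forest	Whole	bacterial	45,676	82,842	0.355
Forest	Whole	fungal	16	4,860	0.003
Forest	Whole	bacterial_fungal	4,293	6,313	0.405
Wetland	Whole	all	34,175	64,190	0.347
Wetland	Whole	bacterial	32,944	59,761	0.355
Wetland	Whole	fungal	3	1,750	0.002
Wetland	Whole	bacterial_fungal	1,228	2,679	0.314
Grass	Whole	all	130,126	235,602	0.356
Grass	Whole	bacterial	116,905	221,191	0.346
Grass	Whole	fungal	26	4,216	0.006
Grass	Whole	bacterial_fungal	13,195	10,195	0.564
Desert	Whole	all	17,418	52,058	0.251
Desert	Whole	bacterial	16,970	49,556	0.255
Desert	Whole	fungal	3	2,145	0.001
Desert	Whole	bacterial_fungal	445	357	0.555
Agricultural field	U	all	15,386	33,637	0.314
Agricultural field	U	bacterial	13,467	28,226	0.323
Agricultural field	U	fungal	0	3,080	0.000
Agricultural field	U	bacterial_fungal	1,919	2,331	0.452
Agricultural field	D	all	26,347	50,840	0.341
Agricultural field	D	bacterial	21,427	42,157	0.337
Agricultural field	D	fungal	5	2,444	0.002
Agricultural field	D	bacterial_fungal	4,915	6,239	0.441
Forest	U	all	1,830	4,913	0.271
Forest	U	bacterial	1,628	4,188	0.280
Forest	U	fungal	2	407	0.005
Forest	U	bacterial_fungal	200	318	0.386
Forest	D	all	1,436	4,568	0.239
Forest	D	bacterial	1,346	3,778	0.263
Forest	D	fungal	1	687	0.001
Forest	D	bacterial_fungal	89	103	0.464
Wetland	U	all	777	1,699	0.314
Wetland	U	bacterial	709	1,547	0.314
Wetland	U	fungal	1	59	0.017
Wetland	U	bacterial_fungal	67	93	0.419
Wetland	D	all	545	1,288	0.297
Wetland	D	bacterial	508	1,159	0.305
Wetland	D	fungal	0	85	0.000
Wetland	D	bacterial_fungal	37	44	0.457
Grass	U	all	15,069	42,788	0.260
Grass	U	bacterial	13,609	40,828	0.250
Grass	U	fungal	4	1,195	0.003
Grass	U	bacterial_fungal	1,456	765	0.656
Grass	D	all	9,541	38,090	0.200
Grass	D	bacterial	8,507	36,206	0.190
Grass	D	fungal	0	1,082	0.000
Grass	D	bacterial_fungal	1,034	802	0.563
Desert	U	all	1,316	4,846	0.214
Desert	U	bacterial	1,259	4,510	0.218
Desert	U	fungal	1	283	0.004
Desert	U	bacterial_fungal	56	53	0.514
Desert	D	all	403	1,294	0.237
Desert	D	bacterial	363	1,059	0.255
Desert	D	fungal	1	197	0.005
Desert	D	bacterial_fungal	39	38	0.507
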