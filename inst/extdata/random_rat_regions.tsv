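locus_name	species	chromosome	start	end	role	carcinogen	overlap_group
random_1	rat	RNO9	20,000,000	44,322,711	rat_source	none	
random_1	human	chr2	97,158,323	106,711,249	human_ortholog	none	
random_1	human	chr6	56,223,874	73,919,999	human_ortholog	none	
random_1	human	chr2	189,182,486	189,878,065	human_ortholog	none	
random_1	human	chr13	103,235,577	103,556,495	human_ortholog	none	
random_1	human	chr2	128,848,569	129,254,860	human_ortholog	none	
random_2	rat	RNO15	60,000,001	84322711	rat_source	none	
random_2	human	chr13	53,226,266	74,878,291	human_ortholog	none	
random_2	human	chr13	42,064,282	42,529,444	human_ortholog	none	
random_3	rat	RNO16	68,621,246	92,943,956	rat_source	none	
random_3	human	chr13	103,539,456	115,092,822	human_ortholog	none	
random_3	human	chr8	36,627,241	42,308,840	human_ortholog	none	
random_3	human	chr8	638,582	6,693,649	human_ortholog	none	
random_3	human	chr8	42,690,588	43,056,179	human_ortholog	none	
random_3	human	chr13	52,753,969	53,050,606	human_ortholog	none	
random_4	rat	RNO9	91,398,460	115,721,170	rat_source	none	
random_4	human	chr5	98,385,946	110,062,886	human_ortholog	none	
random_4	human	chr18	612,848	9,957,727	human_ortholog	none	
random_4	human	chr2	240,340,012	242,806,427	human_ortholog	none	
random_5	rat	RNO13	55,373,307	79,696,017	rat_source	none	
random_5	human	chr1	169,844,936	194,938,667	human_ortholog	none	
random_6	rat	RNO11	39,408,000	63,730,710	rat_source	none	
random_6	human	chr3	95,108,010	118,895,417	human_ortholog	none	
random_7	rat	RNO17	68,384,015	92,706,725	rat_source	none	
random_7	human	chr10	138,740	22,530,353	human_ortholog	none	
random_7	human	chr1	236,673,870	240,084,642	human_ortholog	none	
random_8	rat	RNO3	12,585,543	36,908,253	rat_source	none	
random_8	human	chr2	140,246,548	155,465,845	human_ortholog	none	
random_8	human	chr9	123,526,091	129,443,210	human_ortholog	none	
random_9	rat	RNO19	34,130,390	58,453,100	rat_source	none	
random_9	human	chr16	66,968,878	90,107,058	human_ortholog	none	
random_9	human	chr10	33,502,588	35,153,585	human_ortholog	none	
random_9	human	chr1	229,402,942	235,324,796	human_ortholog	none	
random_9	human	chr4	150,548,912	150,855,848	human_ortholog	none	
random_10	rat	RNO12	18,203,110	42,525,820	rat_source	none	
random_10	human	chr12	110,503,298	120,870,994	human_ortholog	none	
random_10	human	chr12	121,578,435	132,335,900	human_ortholog	none	
random_10	human	chr7	66,878,689	71,941,664	human_ortholog	none	
random_10	human	chr7	101,137,811	102,184,451	human_ortholog	none	
random_10	human	chr7	99,995,220	100,350,712	human_ortholog	none	
random_10	human	chr7	72,707,443	74,223,683	human_ortholog	none	
random_10	human	chr7	75,027,443	76,145,496	human_ortholog	none	
random_11	rat	RNO20	30,416,373	54,739,083	rat_source	none	
random_11	human	chr6	101,086,446	116,620,662	human_ortholog	none	
random_11	human	chr6	117,266,139	123,147,126	human_ortholog	none	
random_11	human	chr2	109,065,537	109,613,060	human_ortholog	none	
random_11	human	chr6	116,688,407	116,905,609	human_ortholog	none	
random_12	rat	RNO13	955,085	25,277,795	rat_source	none	
random_12	human	chr18	58,351,906	63,553,937	human_ortholog	none	
random_12	human	chr2	124,758,685	125,682,595	human_ortholog	none	
random_13	rat	RNO1	1,136,860	25,459,569	rat_source	none	
random_13	human	chr6	128,011,342	150,185,813	human_ortholog	none	
random_13	human	chr6	123,315,387	124,317,854	human_ortholog	none	
random_14	rat	RNO2	182,078,762	206,401,472	rat_source	none	
random_14	human	chr1	107,259,608	154,441,176	human_ortholog	none	
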