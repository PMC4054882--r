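locus_name	species	chromosome	start	end	role	carcinogen	overlap_group
Mcs1a	rat	RNO2	5,601,528	10,539,344	rat_source	DMBA	
Mcs1a	human	chr5	89,216,702	93,113,337	human_ortholog	DMBA	
Mcs1b	rat	RNO2	42,364,155	44,195,382	rat_source	DMBA	
Mcs1b	human	chr5	54,816,178	57,003,049	human_ortholog	DMBA	
Mcs1c	rat	RNO2	13,909,383	20,666,092	rat_source	DMBA	
Mcs1c	human	chr5	81,891,633	86,857,442	human_ortholog	DMBA	
Mcs1c	human	chr5	86,171,198	86,251,067	human_ortholog	DMBA	
Mcs2	rat	RNO7	4,936,704	86,028,057	rat_source	DMBA	Mcs6,Emca4
Mcs2	human	chr12	57,316,160	108,177,690	human_ortholog	DMBA	Mcs6,Emca4
Mcs2	human	chr8	97,242,984	115,650,989	human_ortholog	DMBA	Mcs6,Emca4
Mcs2	human	chr19	281,161	2,497,331	human_ortholog	DMBA	Mcs6,Emca4
Mcs2	human	chr19	15,059,910	15,808,112	human_ortholog	DMBA	Mcs6,Emca4
Mcs3	rat	RNO1	90,282,174	156,954,117	rat_source	DMBA	
Mcs3	human	chr15	80,282,370	102,265,870	human_ortholog	DMBA	
Mcs3	human	chr15	25,574,935	28,567,541	human_ortholog	DMBA	
Mcs3	human	chr11	17,403,456	22,898,646	human_ortholog	DMBA	
Mcs3	human	chr11	74,958,193	89,350,902	human_ortholog	DMBA	
Mcs3	human	chr19	48,799,986	51,921,957	human_ortholog	DMBA	
Mcs3	human	chr19	28,701,413	30,656,003	human_ortholog	DMBA	
Mcs4	rat	RNO8	28,414,100	72,403,639	rat_source	DMBA	
Mcs4	human	chr11	107,453,990	132,383,506	human_ortholog	DMBA	
Mcs4	human	chr15	62,105,069	76,028,735	human_ortholog	DMBA	
Mcs4	human	chr15	76,091,658	78,185,872	human_ortholog	DMBA	
Mcs4	human	chr15	78,380,119	78,998,961	human_ortholog	DMBA	
Mcs4	human	chr15	51,349,646	51,942,505	human_ortholog	DMBA	
Mcs5a1	rat	RNO5	61,634,727	61,666,739	rat_source	DMBA	Mcstm1,Emca8
Mcs5a1	human	chr9	37,562,516	37,589,491	human_ortholog	DMBA	Mcstm1,Emca8
Mcs5a2	rat	RNO5	61,667,053	61,751,614	rat_source	DMBA	Mcstm1,Emca8
Mcs5a2	human	chr9	37,590,988	37,654,512	human_ortholog	DMBA	Mcstm1,Emca8
Mcs5b	rat	RNO5	65,498,190	67,464,050	rat_source	DMBA	Mcstm1,Emca8
Mcs5b	human	chr9	103,492,712	105,220,552	human_ortholog	DMBA	Mcstm1,Emca8
Mcs5c	rat	RNO5	81,118,457	81,295,367	rat_source	DMBA	Mcstm1,Emca8
Mcs5c	human	chr9	118,231,525	118,416,951	human_ortholog	DMBA	Mcstm1,Emca8
Mcs5c	human	chr12	72,033,141	72,033,263	human_ortholog	DMBA	Mcstm1,Emca8
Mcs6	rat	RNO7	22,382,725	55,384,873	rat_source	DMBA	Mcs2
Mcs6	human	chr12	71,270,266	105,502,699	human_ortholog	DMBA	Mcs2
Mcs7	rat	RNO10	89,575,060	100,335,500	rat_source	DMBA	Mcsta1
Mcs7	human	chr17	40,183,547	67,946,104	human_ortholog	DMBA	Mcsta1
Mcs8	rat	RNO14	12,386,493	26,416,791	rat_source	DMBA	
Mcs8	human	chr4	65,556,457	81,559,483	human_ortholog	DMBA	
Mcsm1	rat	RNO6	34,039,303	114,032,192	rat_source	DMBA	Emca7
Mcsm1	human	chr14	25,151,530	80,417,386	human_ortholog	DMBA	Emca7
Mcsm1	human	chr2	33,441	18,603,019	human_ortholog	DMBA	Emca7
Mcsm1	human	chr7	12,561,599	19,619,365	human_ortholog	DMBA	Emca7
Mcsm1	human	chr7	107,770,320	111,916,436	human_ortholog	DMBA	Emca7
Mcstm1	rat	RNO5	19,206,257	157,657,360	rat_source	DMBA	Mcs5,Emca1,Emca8
Mcstm1	human	chr1	20,301,931	59,012,763	human_ortholog	DMBA	Mcs5,Emca1,Emca8
Mcstm1	human	chr1	59,119,520	67,602,141	human_ortholog	DMBA	Mcs5,Emca1,Emca8
Mcstm1	human	chr9	27,325,071	123,488,955	human_ortholog	DMBA	Mcs5,Emca1,Emca8
Mcstm1	human	chr6	87,792,854	100,245,025	human_ortholog	DMBA	Mcs5,Emca1,Emca8
Mcstm1	human	chr8	87,055,841	97,247,307	human_ortholog	DMBA	Mcs5,Emca1,Emca8
Mcstm1	human	chr8	58,994,818	62,700,945	human_ortholog	DMBA	Mcs5,Emca1,Emca8
Mcstm2	rat	RNO18	32,458,819	86,863,412	rat_source	DMBA	Emca2
Mcstm2	human	chr18	10,202,644	13,129,349	human_ortholog	DMBA	Emca2
Mcstm2	human	chr18	41,356,963	54,158,113	human_ortholog	DMBA	Emca2
Mcstm2	human	chr18	54,267,924	58,201,561	human_ortholog	DMBA	Emca2
Mcstm2	human	chr18	66,912,039	78,010,606	human_ortholog	DMBA	Emca2
Mcstm2	human	chr5	112,300,500	130,363,372	human_ortholog	DMBA	Emca2
Mcstm2	human	chr5	142,780,151	147,624,793	human_ortholog	DMBA	Emca2
Mcstm2	human	chr5	147,647,196	150,176,352	human_ortholog	DMBA	Emca2
Mcsta1	rat	RNO10	9,762,188	108,776,963	rat_source	DMBA	Mcs7
Mcsta1	human	chr5	130,482,861	173,663,969	human_ortholog	DMBA	Mcs7
Mcsta1	human	chr5	177,530,539	180,675,650	human_ortholog	DMBA	Mcs7
Mcsta1	human	chr17	690,639	15,624,409	human_ortholog	DMBA	Mcs7
Mcsta1	human	chr17	16,916,926	20,222,700	human_ortholog	DMBA	Mcs7
Mcsta1	human	chr17	25,525,650	78,247,249	human_ortholog	DMBA	Mcs7
Mcsta1	human	chr16	78,402	6,094,950	human_ortholog	DMBA	Mcs7
Emca1	rat	RNO5	103,677,474	155,121,024	rat_source	estradiol	Mcstm1,Emca8
Emca1	human	chr1	23,607,020	59,012,763	human_ortholog	estradiol	Mcstm1,Emca8
Emca1	human	chr1	59,119,520	67,602,141	human_ortholog	estradiol	Mcstm1,Emca8
Emca1	human	chr9	17,037,252	27,300,264	human_ortholog	estradiol	Mcstm1,Emca8
Emca2	rat	RNO18	18,562,643	66,652,947	rat_source	estradiol	Mcstm2
Emca2	human	chr5	110,259,180	130,363,372	human_ortholog	estradiol	Mcstm2
Emca2	human	chr5	137,224,929	147,624,793	human_ortholog	estradiol	Mcstm2
Emca2	human	chr5	147,647,196	150,176,352	human_ortholog	estradiol	Mcstm2
Emca2	human	chr18	10,202,644	13,129,349	human_ortholog	estradiol	Mcstm2
Emca2	human	chr18	35,982,130	41,016,602	human_ortholog	estradiol	Mcstm2
Emca2	human	chr18	52,597,120	54,158,113	human_ortholog	estradiol	Mcstm2
Emca2	human	chr18	54,267,924	58,201,561	human_ortholog	estradiol	Mcstm2
Emca2	human	chr2	127,805,417	128,786,719	human_ortholog	estradiol	Mcstm2
Emca4	rat	RNO7	66,201,980	107,428,439	rat_source	estradiol	Mcs2
Emca4	human	chr8	97,242,984	137,409,536	human_ortholog	estradiol	Mcs2
Emca4	human	chr12	57,316,160	59,093,375	human_ortholog	estradiol	Mcs2
Emca5	rat	RNO3	41,054,012	171,063,335	rat_source	estradiol	
Emca5	human	chr20	1,746,912	62,907,504	human_ortholog	estradiol	
Emca5	human	chr2	110,841,402	113,650,057	human_ortholog	estradiol	
Emca5	human	chr2	159,530,076	188,395,371	human_ortholog	estradiol	
Emca5	human	chr11	26,296,319	57,753,858	human_ortholog	estradiol	
Emca5	human	chr15	32,905,485	34,664,466	human_ortholog	estradiol	
Emca5	human	chr15	34,933,152	51,298,144	human_ortholog	estradiol	
Emca6	rat	RNO4	41,729,583	159,115,617	rat_source	estradiol	
Emca6	human	chr7	23,252,368	33,103,107	human_ortholog	estradiol	
Emca6	human	chr7	115,026,301	150,558,396	human_ortholog	estradiol	
Emca6	human	chr3	88,756	12,883,445	human_ortholog	estradiol	
Emca6	human	chr3	13,004,609	15,163,132	human_ortholog	estradiol	
Emca6	human	chr3	64,018,604	75,322,612	human_ortholog	estradiol	
Emca6	human	chr3	125,977,400	128,219,297	human_ortholog	estradiol	
Emca6	human	chr2	68,713,643	89,165,869	human_ortholog	estradiol	
Emca6	human	chr4	89,504,626	95,273,083	human_ortholog	estradiol	
Emca6	human	chr4	120,978,632	122,320,931	human_ortholog	estradiol	
Emca6	human	chr12	156,786	2,821,588	human_ortholog	estradiol	
Emca6	human	chr10	43,277,230	46,218,580	human_ortholog	estradiol	
Emca7	rat	RNO6	2,802,670	111,967,837	rat_source	estradiol	Mcsm1
Emca7	human	chr14	25,151,530	78,362,253	human_ortholog	estradiol	Mcsm1
Emca7	human	chr2	33,441	35,642,893	human_ortholog	estradiol	Mcsm1
Emca7	human	chr2	38,644,737	51,698,454	human_ortholog	estradiol	Mcsm1
Emca7	human	chr7	12,561,599	19,619,365	human_ortholog	estradiol	Mcsm1
Emca7	human	chr7	105,197,211	111,916,436	human_ortholog	estradiol	Mcsm1
Emca8	rat	RNO5	52,434,178	148,460,381	rat_source	estradiol	Mcs5,Mcstm1,Emca1
Emca8	human	chr9	6,756,013	27,300,264	human_ortholog	estradiol	Mcs5,Mcstm1,Emca1
Emca8	human	chr9	27,925,947	123,488,955	human_ortholog	estradiol	Mcs5,Mcstm1,Emca1
Emca8	human	chr1	33,159,021	59,012,763	human_ortholog	estradiol	Mcs5,Mcstm1,Emca1
Emca8	human	chr1	59,119,520	67,602,141	human_ortholog	estradiol	Mcs5,Mcstm1,Emca1
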