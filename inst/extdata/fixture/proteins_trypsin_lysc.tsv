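accession	confidence	n_unique_peptides	126	127N	127C	128N	128C	129N	129C	130N	130C	131N	131C	132N
SYN0001	high	5	1033500	950998	779634	1000190	495538	483372	453397	415090	265361	234561	202821	208461
SYN0002	high	7	74783.2	77874.3	71757.8	80140.2	162009	143532	152959	148776	349473	356440	293022	297531
SYN0003	high	5	62369.3	72556.6	64350.7	75819.6	131363	128170	129717	118991	276572	264825	242055	231441
SYN0004	high	4	334893	360825	345819	379220	201313	194185	171580	171728	93617.3	101762	85746.5	83003.7
SYN0005	high	7	194209	199949	196812	212705	199434	206464	199821	162452	224702	210359	179852	170799
SYN0006	high	8	36481.8	42361.8	38869.2	42017.4	79143.1	89135.2	74490	71649.7	173034	159520	146314	141455
SYN0007	high	4	34300.6	39603.9	34612	40172.2	38403	38413.3	32740.8	30119.1	38747.7	36465.6	33531.7	34534.1
SYN0008	high	5	288628	341546	247821	290395	870634	886699	735976	792906	329073	284716	265264	276742
SYN0009	high	5	278448	292064	260052	275615	278929	267389	252184	243430	263280	292394	257822	258500
SYN0010	high	7	8863.09	10337.9	8299.48	8795.01	19113.1	17005.5	17061.7	16073.3	36657.9	37655.1	33184.7	33438.7
SYN0011	high	5	95912.2	96463.5	85784.1	93202.8	46000.5	45901.8	42324.7	38783.8	22534.9	22524	20865.4	20346.6
SYN0012	high	8	83160.5	87213.2	77732.5	79382.3	149870	165809	163180	138850	338140	367314	280928	283300
SYN0013	high	5	840487	991841	898570	886699	468267	436721	413975	411026	220770	232870	203738	225846
SYN0014	high	5	64496.6	78075.9	57756.6	65764.9	124066	133326	118008	119088	275357	263322	239234	249673
SYN0015	high	6	138157	146618	125132	146359	253813	279993	253298		600649	608986	507472	514756
SYN0016	high	10	22711.3	27479.2	23105.5	26062.7	49666	51136.4	46536.7	44540.3	106929	92559.3	92593.3	94023.6
SYN0017	high	4	37435.5	40062.5	33529.1	34251.7	73631.1	78065.4	72498	72678.3	148198	151814	138558	138127
SYN0018	high	3	53466.3	56386.2	47194.4	49733.7	99360.7	91364.5	92932.7	89824.8	194033	194428	184368	177304
SYN0019	high	7	53984.5	68328.6	55672.9	59122.6	184397	175032	152014	146410	59399.4	57748.7	53660.8	47917.7
SYN0020	high	5	41374.4	42471.2	38765.8	43234.8	81702.9	85977	84820.3	69938.5	159565	175539	158065	148193
SYN0021	high	7	115726	122378	109329	111448	55804.1	50974.4	54831.9	49422.8	30563.6	28789.5		26030.3
SYN0022	high	4	73528.4	78891.6	72142.4	75066	36521	34441.3	33045	29053.3	17769.3	18732.3	18885.9	16272.5
SYN0023	high	4	6667.15	8267.32	5922.82	7333.41	12216.7	13462		12116.6	29093.4	25530.6	24894	23417.2
SYN0024	high	3	638646	651889	588851	698461	318403	340711	283559	314629	164020	164136	147971	165442
SYN0025	high	4	347369	352050	271947	312227	140681	160503	139983	134584	80676.9	80137.3	74560.3	66474.2
SYN0026	high	7	26328.4	28386.2	23212.4	25267.5	53661.5	52037.9	48541.2	45187.6	104593	108313	95270	89730.2
SYN0027	high	6	34625.3	40851.2	30471.4	37808.9	101738	98936.1	85466.8	88776.8	37263.2	36265.3	30715.6	33958.9
SYN0028	high	3	145778	174132		160754	303685	283462	277580	253159	589591	609322	569339	578170
SYN0029	high	5	367440	379662	353858	412404	170596	170741	186151	152422	88151	82501.1	72380.4	80129.7
SYN0030	high	13	444235	500884	406936	501889	217318	219302	186932	199586	113269	117306	116701	104706
SYN0031	high	2	28249.7	30869.2	27857.9	29566.5	55130.4	58824.6	53297.7	51998.4	127410	127663	102607	106470
SYN0032	high	2	97528.6		91511	102421	93207.5	91404.7	86550.2	89736.6	100060	100804	93643.6	96062.2
SYN0033	high	5	360595	376671	330957	400916	726273	728612	676366	601376	1467100	1384520	1286040	1269090
SYN0034	high	5	30504.4	36177.5	29049.9	35628	65061.5	64193	59401.1	56784.3	123324	132117	111523	110564
SYN0035	high	9	37371.3	43802.6	34421	38691.2	37375.1	38940.1	34903.8	37035.3	40529	38545.1	36708.9	35252.3
SYN0036	high	6	24298.5	26687	22671.4	26792.4	52460.3	55016.6	50300.4	47728.3	101097	103517	98455.3	94554.4
SYN0037	high	7	72373.4	80500.3	71435.8	69090.6	142190	139429	118075	126931	281280	269156	257834	249834
SYN0038	high	4	140750	154119	117960	136908	68056.6	70759.3	63605.4	58844.1	34827.5	34202.7	28203.8	30049.4
SYN0039	high	5	16285.1	17954.3	16186.9	17316.4	17793.9	16012.6	14928.3	15503.7	18265.6	16756.9	16192	15233.2
SYN0040	high	9	195555	212301	200768	211836	102785	104995	98900.6	88021.1	50905.2	49929.3	45611	48560.8
SYN0041	high	6	20159.9	22600.7	19121.4	20982.8	22519.6	18981.3	19137.7		19973.7	19602.1	19197.9	19677.1
SYN0042	high	6	27033.9	28960.1	23649.9	27843.7	14393.2	13118.8	12330.4	12022.3	6897.36	6820.17	6539.45	6520.32
SYN0043	high	9	57614.2	61992.7	57668.2	61195.2	30463.4	32947.6	29498.5	28510.4	16232.3	15042.5	13109.4	12855.2
SYN0044	high	5	27115.2	30334	23375.7	28726.1	54289.6	53492.1	54218.9	44454.6	123469	116455	96039	98435.3
SYN0045	high	4	162487	202587	158948	184664	340547	350056	351195	336349	825193	697556	698134	611752
SYN0046	high	8	166089	185961	155664	165122	90705.4	86422.7	69776.6	78405.7	46816.4	44580.9	38902	42253.4
SYN0047	high	2	33555.7	37781.3	29825.3	35394.8	68770.9	68237.8	60635.1	61424.5	147236	135922	122352	118853
SYN0048	high	9	72247.7	67309.5	55165.5	65897.1	123582	124304	110861	121797	282548	239138	214499	217343
SYN0049	high	5	15052.1	15676.6	12773.4	14826.5	36106.9	40911.9	38205.4	39329.4	14908.9	14240.6	14695.4	13946.7
SYN0050	high	8	128073	131037	122260	139958	123069	132282	121693	111162	142103	133707	124543	114683
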