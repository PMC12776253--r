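accession	confidence	n_unique_peptides	126	127N	127C	128N	128C	129N	129C	130N	130C	131N	131C	132N
SYN0001	high	5	832260	907702	874129	889517	379579	451554	426152	453859	212987	228879	202004	198081
SYN0002	high	6	76115.7	73782.6	74528.4	79643.4	141133	131513	156257	165123	338629	310973	275816	312917
SYN0003	high	12	56638.1	52033	53210.5	60587.7		99286.8	103531	119795	236466	237962	213471	209054
SYN0004	high	4	345456	362739	383923	396468	169488	204980	187336	186312	104323	97896.4	88783.3	96844.4
SYN0005	high	9	141392	148387	146462	164314	128311	143464	142721	158910	158153	145119	143375	149951
SYN0006	high	7	25435.6	20975.3	24641.6	26475.2	43306.9	45249.8	46338	52331.2	108557	93490.9	100927	94540.8
SYN0007	high	8	50835.9	51300.8	53927.8	60261	46323.8	53018.7	58395.7	56410.6	55351.4	51311.1	51328.2	50746
SYN0008	high	8	210459	218753	219736	234558	566552	565591		617566	228843	216807	218780	213520
SYN0009	high	6	188315	201638	218129	239392	179008	224505	219626	217587	221909	225038	192757	194863
SYN0010	high	4	12591.9	13160.1	13567.5	15274.6	23341.7	24626.5	27734.5	25714.5	58094.6	54083.8	56468.7	50883.7
SYN0011	high	6	79025	78164.2	80271.6	88118.2	35265.6	40921.6	38342.1	46835.7	21700.2	20447	18817.2	18397.9
SYN0012	high	5	66949	62188.7		76815.2	119003	126079	140857	138592	310042	289665	234321	268986
SYN0013	high	5	1003380	1006340	1023880	1091160	487237		508345	565289	269622	288709	230514	264481
SYN0014	high	5	41581	48026.9	44393.8	46852.9	89230.9	87931.7		91158.5	189885	206877	162497	179698
SYN0015	high	9	87873.6	81593.1	91749.4	102095	151969	184029	180868	197589	370657	362797	350745	317053
SYN0016	high	7	28191.3	29178.9	32855.1	35169.7	53741.8	63941.8	59438.4	65749.8	126914	135765	117399	120787
SYN0017	high	5	21479.8	23189.8	21940.9	23715.8	36743.7	40402.6	50855.7	46739.9	93877.4	91625.9	86444.2	84214.3
SYN0018	high	3	65040.5	62260.5	71169	69576.1	112139	138924	144169	143944	314382		259773	240809
SYN0019	high	3	41579.9	40548.9	44318.6	45588.5	108696	111199		134418	45083.4	41584.2	38541.9	43448.1
SYN0020	high	4	34734.9	38848.8	41634.2	40772.4	68085.6	68943.2	77788.7	76876.1	165198	139931	152588	147047
SYN0021	high	4	118220	118647	126832	129954	55875.2	55227.2	57900.8	63100.6	31896.9	30367.5	27693.5	26452.4
SYN0022	high	5	69403.2	68818.4	73909.2	78482.3	36394.1	33838.3	35347.4	39524.9	18961.5	20002.8	16241	16972.7
SYN0023	high	6	6651.04	6963.67	6589.08	7177.68	12607.3	13301.6	14456.2	14136.7	31307.1	28285.4	27401.5	28860.5
SYN0024	high	5	564338	553027	586716	613003	261175	281912	289774	316974	148003	158243	137739	143818
SYN0025	high	8	263939	248705	265416	296901	116341	120923	136656	138987	67808	67305.4	60009.3	60240.3
SYN0026	high	5	22296.1	20811.7	22093	23839.1	37095.4	42199.3	41302.5	43400.1	91086.7	85637.9	89305.9	83924.1
SYN0027	high	6	27922.7	28421.9	29676.8	30901.2		82875.1	78938.3	85498.6	32853	30062.7	29451.2	27427.3
SYN0028	high	5	132900	134646	154611	162670	256932	253247	293965	329251	565558	614635	542361	534146
SYN0029	high	9	432648	460452	460064	458679	205719	202336	207553	241926		123023	100449	98533.2
SYN0030	high	4	362738	378447	374292	424856	172539	177903	220276	192387	104600	106292	96584.4	78629.1
SYN0031	high	4	41134.4	40577.5	43580.6	43198.8	75398.6	78352.3	84683.2	85193.9	175956	164222	153429	141283
SYN0032	high	9	127656	115866	123830	141182	107074	120679	123691	122713	135563	121936	114534	124063
SYN0033	high	5	276035	261904	282877	305051	510966	537280	564407	583572	1211810	1135550	935361	969180
SYN0034	high	5	31710.8		31167.2	30605	53794.9	53623.6	58602.6	64908.8	135735	135806	117702	123303
SYN0035	high	7	46226.2	43395.4	46292.7	46803.6	39579	44438.5	45727	49429.3	51606.1	45230	40794.7	39794
SYN0036	high	4	19251.9	18876.4	20774.3	21672.8	36552.8	38132.7	41416.9	41902.3	78367.1	85205.9	80539.1	77836.3
SYN0037	high	5	48842.9	46970.9	50127.4	53165.8	83655.8	89685.4	91747.1	102585	215736	186911	177257	167468
SYN0038	high	10	140108	121937	141162	125980	67890.6	59737.3	71534.8	72885.1	36047.1		31357.8	30160.9
SYN0039	high	4	21139.4	19143.6	20609.8	22372.2	18411.3	20353	21669.3	22876.3	23469.7	20828.9	18892.6	20465.9
SYN0040	high	5	126055	129657	129982	140508	62116.6	68408.5		71061.9	33099.2	34667.7	27659.4	31231.4
SYN0041	high	10	21122.6	20289	22504.3	21653.1	18432.1	18402.1	20784.6	22914.1	23332.1	19089.3	20067.7	20704.1
SYN0042	high	5	21804.2	21937.6	23833.3	25129.9	10054	11346.7		11554.3	6710.1	5577.58	5245.08	5373.66
SYN0043	high	6	55596.6	51679.3	56705	63452.3	24041.5	27272.5	30193.8	28172.3	13616.4	15075.3	13374.3	12922.7
SYN0044	high	6	19004.7	19950.1	21435.8	23534.8	35919.4	37704	42948.4	40808.5	90454.8	89185.9	74809.8	84342.8
SYN0045	high	6	72514.6	75395.4	75965.2	88430	141013	161948	150308	162508	322440	298111	260268	298955
SYN0046	high	6		162688	189686	220746	84305.5	96309.3	96223.3	105758	52002.6	49399.8	46002.4	48826.3
SYN0047	high	7	33858.5	35201	39101.1	42002.2	62635.7	70226.4	71834.4	73082.3	174645	143191	146099	135614
SYN0048	high	7	70675.2	65957.4	71089.4	71121.5	139350	129541	137377	144730	308839	292528	276434	
SYN0049	high	6	28225.8	30068.8	28201.5	33615	76105.2		84784.8	92563.5	31404.7	30618.7	27320.6	30221.7
SYN0050	high	3	151845	153811	154298	173336	136187	146067	161032	181368	179524	162578	156188	136378
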