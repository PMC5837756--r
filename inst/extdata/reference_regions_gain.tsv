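# Validated recurrent gain CNA regions with genes, as printed in a published
# young-onset breast cancer study (coordinates behave as half-open:
# Size = End - Start).  Size1/Size2 are discovery/validation patient counts.
Chr	InnerStart	InnerEnd	InnerSize	OuterStart	OuterEnd	OuterSize	GeneSymbols	Size1	Size2
1	84551640	84565561	13921	84481190	84729446	248256	SAMD13	5	6
1	143607802	143609034	1232	143607067	143609055	1988	PDE4DIP	20	30
1	191374290	191385577	11287	191359529	191405183	45654	CDC73	40	50
1	191385797	191402004	16207	191359529	191405183	45654	CDC73	40	50
1	222004315	222004925	610	221990859	222005526	14667	CAPN2	48	47
3	176423680	176427601	3921	176415397	176428705	13308	NAALADL2	18	22
3	176428607	176428705	98	176415397	176470832	55435	NAALADL2	18	22
5	22246497	22346803	100306	22194503	22414425	219922	CDH12	12	11
6	34625387	34634997	9610	34624907	34656516	31609	SPDEF	9	9
7	134782461	134787038	4577	134782461	134792291	9830	CNOT4	11	13
7	142150844	142154230	3386	142150819	142154515	3696	PRSS1	7	10
8	40695071	40697114	2043	40693570	40699795	6225	ZMAT4	17	16
9	93166194	93261927	95733	93157333	93373420	216087	NFIL3	5	7
10	5737990	5742226	4236	5736767	5744158	7391	ASB13	24	32
10	14598341	14600566	2225	14477106	14629604	152498	FAM107B	19	27
11	4931741	4932834	1093	4931741	4932966	1225	MMP26; OR51A2	7	11
12	180797	191614	10817	180797	195197	14400	SLC6A12	14	24
12	7895693	7897774	2081	7895693	7897774	2081	SLC2A14	13	23
12	7899067	7905082	6015	7899067	7909593	10526	SLC2A14	13	23
13	112354883	112363586	8703	112333434	112363586	30152	C13orf35	10	7
13	113356126	113365589	9463	113345036	113371998	26962	ATP4B	10	9
17	43751830	43753351	1521	43722185	43756717	34532	SKAP1	9	14
17	45136676	45139395	2719	45134175	45142242	8067	SLC35B1	21	18
18	9549925	9575313	25388	9417006	9594232	177226	PPP4R1	5	7
18	43704001	43707399	3398	43703934	43707399	3465	SMAD2	6	6
19	40629439	40647918	18479	40620640	40702499	81859	FFAR2	13	13
19	60890917	60901410	10493	60890917	60904859	13942	EPN1	8	11
20	14741416	14743670	2254	14741416	14743754	2338	MACROD2	8	10
20	41215727	41219453	3726	41202818	41220578	17760	PTPRT	12	18
22	20146692	20170596	23904	20145867	20170766	24899	PI4KAP2; TMEM191C	7	15
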