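# Validated recurrent loss CNA regions with genes, as printed in a published
# young-onset breast cancer study (coordinates behave as half-open:
# Size = End - Start).  Size1/Size2 are discovery/validation patient counts.
Chr	InnerStart	InnerEnd	InnerSize	OuterStart	OuterEnd	OuterSize	GeneSymbols	Size1	Size2
2	97507180	97517476	10296	97507180	97520698	13518	ANKRD36B	5	5
3	62243538	62257523	13985	62242606	62277516	34910	PTPRG	6	6
4	59521	61566	2045	59521	64435	4914	ZNF718; ZNF595	13	6
7	38296343	38297866	1523	38295506	38297939	2433	TRGV11	18	22
8	14388851	14391732	2881	14385622	14391732	6110	SGCZ	23	18
9	5027454	5029342	1888	5027454	5030334	2880	JAK2	7	11
10	89710114	89713882	3768	89708179	89713882	5703	PTENP1; PTEN	10	10
17	21245986	21253816	7830	21227031	21271210	44179	KCNJ12	15	9
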