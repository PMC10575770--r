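gene	origin	family	label	chrom	pos	ref	alt	aa_change	dbsnp	maf_nfe	sift	polyphen	tier	notes
KMT2C	inherited	19	MAP	7	151932996	C	T	p.G892E	rs372408170	0.0001	D	D	1	DDG2P mono-allelic probable
ANKRD11	inherited	10	NAP/Diagnosis	16	89346774	G	T	p.P2059H	rs117997391	0.0075	D	D	1	DDG2P mono-allelic confirmed
SETD2	inherited	14	MAP/Diagnosis	3	47165380	G	A	p.S205F	.	.	D	P	1	DDG2P mono-allelic probable
SETD2	inherited	10	NAP/Diagnosis	3	47164711	C	T	p.R428H	rs201984344	0.0004	D	D	1	DDG2P mono-allelic probable
ATP2B2	inherited	15	BAP	3	10392216	G	A	p.R683C	rs754680596	.	D	D	1	SFARI gene 2
CUX1	inherited	16	MAP/Diagnosis	7	101921292	A	C	p.K530Q	rs118010189	0.0071	D	D	1	DDG2P possible
JADE2	inherited	14	NAP	5	133901944	C	T	p.R370C	rs137957798	0.0005	D	D	2	.
MTOR	inherited	25	NAP	1	11272478	T	C	p.Y1151C	rs151082401	0.0003	D	D	1	DDG2P mono-allelic confirmed
BRPF1	inherited	10	NAP/Diagnosis	3	9783082	G	A	p.V605M	.	.	D	P	1	DDG2P mono-allelic confirmed
ESR1	inherited	10	NAP/Diagnosis	6	152265352	C	T	p.R269C	rs142712646	0.0008	D	D	2	.
MAP2	inherited	16	MAP/Diagnosis	2	210559050	G	A	p.G719D	rs148922251	0.0051	D	D	2	.
SEMA3F	inherited	22	MAP	3	50225538	C	T	p.P684L	rs754678639	.	D	D	2	.
YTHDC1	inherited	28	BAP/Diagnosis	4	69203301	C	A	p.D150Y	rs186920853	.	D	D	1	DBDGD score 2
CHD7	inherited	19	Diagnosis	8	61707624	G	T	p.D726Y	rs748119797	.	D	D	1	DDG2P mono-allelic confirmed
SON	inherited	19	Diagnosis	21	34923617	A	G	p.T694A	rs141608426	0.0034	D	D	1	DDG2P mono-allelic confirmed
PREX1	inherited	3	Diagnosis	20	47309282	C	T	p.G322S	rs202212653	.	D	D	1	SFARI gene 2
PTPRT	inherited	10	Diagnosis	20	40735430	G	C	p.T1129R	rs201830301	6.48E-05	D	D	1	SFARI gene 3
RIMS2	inherited	21	Diagnosis	8	104897660	C	T	p.S86F	rs17854256	0.0062	D	P	1	DDG2P mono-allelic probable
KDM5A	inherited	4	Diagnosis	12	430192	G	A	p.P837L	rs745469846	6.48E-05	D	D	1	DDG2P possible
DYNC1H1	de_novo	15	BAP/Diagnosis	14	102509021	C	T	p.P4150L	.	.	D	D	1	DDG2P mono-allelic confirmed
KDM3A	de_novo	4	MAP/Diagnosis	2	86716780	A	G	p.K1191E	.	.	D	D	1	DBDGD score 3
ZBTB18	de_novo	22	Diagnosis	1	244217437	G	C	p.V112L	.	0	D	D	1	printed label "N /Diagnosis"; treated as diagnosis-only
TAF4	de_novo	4	MAP/Diagnosis	20	60640497	C	G	p.A124P	.	.	D	P	2	printed as one row for families 4/21
TAF4	de_novo	21	BAP/Diagnosis	20	60640497	C	G	p.A124P	.	.	D	P	2	printed as one row for families 4/21
CLOCK	inherited	22	BAP	4	56319253	C	G	p.E392Q	rs373421741	.	D	P	2	.
JAG1	inherited	19	MAP	20	10621462	T	G	p.R1056S	rs146006022	0	D	P	2	.
NCOR2	inherited	10	NAP/Diagnosis	12	124832388	C	T	p.R1342H	rs36081651	0.0066	D	D	2	.
STXBP5L	inherited	15	BAP	3	120952486	G	A	p.V379M	rs61996323	0.0084	D	D	2	.
TNS3	inherited	15	BAP	7	47331594	G	A	p.T1296M	rs41280696	0.0086	D	D	2	.
TTC28	inherited	14	NAP	22	28426233	G	A	p.R1352C	rs201500299	7.00E-04	D	D	2	.
PTCH1	inherited	19	Diagnosis	9	98242733	G	A	p.P295L	rs370755364	.	D	D	1	DBDGD score 3
PHLPP1	de_novo	7	NAP/Diagnosis	18	60506115	C	-	p.Y624fs	.	.	.	.	2	frameshift deletion
CASKIN1	inherited	19	MAP/Diagnosis	16	2231252	G	A	p.S706L	rs201599923	3.00E-04	D	D	3	.
WDR7	inherited	10	NAP/Diagnosis	18	54547385	C	G	p.A1139G	rs773660280	.	D	D	1	DDG2P probable
FAT3	inherited	14	MAP/Diagnosis	11	92534043	G	T	p.V2622F	rs17615477	0.0054	D	D	3	.
MACF1	inherited	3	NAP/Diagnosis	1	39853641	G	T	p.A2981S	rs144760259	0.0052	D	D	1	DDG2P mono-allelic probable
MACF1	inherited	10	NAP/Diagnosis	1	39763365	G	T	p.C815F	rs148207245	0.0069	D	P	1	DDG2P mono-allelic probable
PCDH1	inherited	15	BAP	5	141243507	G	A	p.R418C	rs143703336	6.48E-05	D	D	3	.
VCAN	inherited	14	NAP	5	82786147	G	T	p.V101L	rs758097509	.	D	D	3	.
PCLO	inherited	11	Diagnosis	7	82584378	G	A	p.T1964M	rs148432464	0	D	P	3	.
PSMD1	inherited	19	Diagnosis	2	232010978	A	G	p.M675V	rs201118764	0	D	D	1	SFARI 1
TP53BP1	inherited	22	Diagnosis	15	43714134	C	A	p.G1340V	rs570488146	.	D	P	3	.
DGKI	de_novo	4	BAP/Diagnosis	7	137531385	C	A	p.G75V	.	.	D	P	3	.
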