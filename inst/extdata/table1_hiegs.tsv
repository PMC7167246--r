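gene	chrom	gene_start	gene_end	rsid	vtype	start	end	length_bp	also_str	pclass	length_flag
KDM4A	1	43650158	43705515	rs2842188	HCONDEL	43656932	43656932	466	FALSE	INTRON	ok
NRXN1	2	49918505	51225575	rs7557525	HCONDEL	50146470	50146470	3405	FALSE	INTRON	ok
NRXN1	2	49918505	51225575	rs7557525	HCONDEL	50146625	50146625	958	FALSE	INTRON	ok
NRXN1	2	49918505	51225575	rs7557525	INSERTION	50827590	50829782	2193	FALSE	NONCODING_EXON	ok
AFF3	2	99545419	100142739	rs71413877	HSD	100080237	100104859	24623	FALSE	INTRON	ok
AFF3	2	99545419	100142739	rs13010010	HCONDEL	99554281	99554281	1250	FALSE	INTRON	ok
THSD7B	2	136765545	137677717	rs2558096	HCONDEL	137333693	137333693	1212	FALSE	INTRON	ok
ARIH2	3	48918821	48986382	rs13096357	INSERTION	48968205	48968380	176	TRUE	NONCODING_EXON	ok
STAB1	3	52495338	52524495	rs4687625	STR_EXPANSION	52509368	52509454	87	FALSE	NONCODING_EXON	ok
SFMBT1	3	52903572	53046750	rs4687625	HCONDEL	52951656	52951656	4034	FALSE	INTRON	ok
FOXP1	3	70952817	71583993	rs11720523	HCONDEL	71460722	71460722	449	FALSE	INTRON	ok
FOXP1	3	70952817	71583993	rs11720523	HCONDEL	71162689	71162689	1760	FALSE	INTRON	ok
CADM2	3	84958981	86074429	rs6770622	HCONDEL	85947229	85947229	1042	FALSE	INTRON	ok
PCCB	3	136250306	136337896	rs9853960	EXON_GAIN	136326325	136326385	60	FALSE	CDS_EXON	convention-ambiguous
TFDP2	3	141944428	142149544	rs10804681	HCONDEL	142144111	142144111	2011	FALSE	INTRON	ok
GRID2	4	92303622	93810157	rs1972860	HCONDEL	92649012	92649012	135	FALSE	INTRON	ok
BANK1	4	101411286	102074812	rs13107325	HCONDEL	101422878	101422878	3650	FALSE	INTRON	ok
BANK1	4	101411286	102074812	rs13107325	HCONDEL	101990081	101990081	4838	FALSE	INTRON	ok
TTC29	4	146706638	146945882	rs6840804	HCONDEL	146796204	146796204	9671	FALSE	INTRON	ok
PDE4D	5	58969038	60522120	rs34426618	INSERTION	60429841	60432132	2292	FALSE	NONCODING_EXON	ok
PAM	5	102753981	103031105	rs76160968	HCONDEL	102883977	102883977	3868	FALSE	INTRON	ok
FBXL17	5	107859035	108382098	rs1438660	HCONDEL	108119106	108119106	959	FALSE	INTRON	ok
CALN1	7	71779491	72447151	rs56150095	HCONDEL	72221700	72221700	2994	FALSE	INTRON	ok
SND1	7	127652180	128092609	rs4731392	HCONDEL	127808446	127808446	749	FALSE	INTRON	ok
EXOC4	7	133253073	134066589	rs1362739	INSERTION	133889352	133895456	6105	FALSE	NONCODING_EXON	ok
SGCZ	8	14089864	15238339	rs13253386	HCONDEL	14090971	14090971	277	FALSE	INTRON	ok
TSNARE1	8	142212080	142403240	rs4976976	STR_EXPANSION	142326108	142326158	51	FALSE	NONCODING_EXON	ok
REEP3	10	63521363	63625123	rs2393967	HCONDEL	63593088	63593088	554	FALSE	INTRON	ok
GRIA4	11	105609994	105982092	rs7116046	HCONDEL	105754761	105754761	3804	FALSE	INTRON	ok
NCAM1	11	112961247	113278436	rs2885208	HCONDEL	113152794	113152794	160	FALSE	INTRON	ok
RERG	12	15107783	15348675	rs55754731	HCONDEL	15107134	15107134	69	FALSE	FLANK	ok
KMT2D	12	49018975	49059774	rs1054442	STR_CONTRACTION	49032866	49032866	60	FALSE	CDS_EXON	ok
PRKD1	14	29576479	30191898	rs971681	HCONDEL	29869703	29869703	1515	FALSE	INTRON	ok
FUT8	14	65410592	65744121	14:66113725_C_A	INSERTION	65457887	65458201	315	FALSE	NONCODING_EXON	ok
RTF1	15	41408408	41483563	rs75322822	HCONDEL	41430384	41430384	1965	FALSE	INTRON	ok
GNB5	15	52115105	52191369	rs7172979	HCONDEL	52177036	52177036	1472	FALSE	INTRON	ok
GNB5	15	52115105	52191369	rs7172979	INSERTION	52121612	52121903	292	FALSE	UTR3	ok
SKAP1	17	48133440	48430275	rs12928404	HCONDEL	48286479	48286479	343	FALSE	INTRON	ok
SKAP1	17	48133440	48430275	rs12928404	HCONDEL	48259161	48259161	53	FALSE	INTRON	ok
DCC	18	52340172	53535903	rs71367283	HCONDEL	52358208	52358208	566	FALSE	INTRON	ok
ZNF584	19	58401504	58418327	rs73068339	INSERTION	58404219	58406377	2159	FALSE	NONCODING_EXON	ok
SLC27A5	19	58479512	58512413	rs73068339	DELETION	58490956	58490956	3235	FALSE	NONCODING_EXON	ok
PHF20	20	35771974	35950381	rs78084033	HCONDEL	35797866	35797866	3808	FALSE	INTRON	ok
STAU1	20	49113339	49188367	rs6019535	EXON_GAIN	49179121	49179244	124	FALSE	UTR5	ok
DDX27	20	49219295	49244077	rs6019535	HCONDEL	49221110	49221110	809	FALSE	INTRON	ok
TRIOBP	22	37696988	37776556	rs4396807	INSERTION	37723443	37724117	675	FALSE	CDS_EXON	ok
EP300	22	41091786	41180079	rs4821995	HCONDEL	41135508	41135508	2279	FALSE	INTRON	ok
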