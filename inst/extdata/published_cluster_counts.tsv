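system	peptaibol	cluster1_frames	cluster1_pct	cluster2_frames	cluster2_pct	cluster3_frames	cluster3_pct
PA4A	Pept-A-IVa	78248	15.6496	9473	1.8946	2950	0.59
PB9A	Pept-B-IXa	111751	22.3502	5859	1.1718	23693	4.7386
PA16A	Pept-A-XVIa	25651	5.1302	34019	6.8038	35953	7.1906
PB16	Pept-B-XVI	159963	31.9926	7172	1.4344	9650	1.93
PA25B	Pept-A-XXVb	58324	11.6648	52182	10.4364	42007	8.4014
PB27	Pept-B-XXVII	91004	18.2008	948	0.1896	1176	0.2352
PA19A	Pept-A-XIXa	32293	6.4586	8099	1.6198	20047	4.0094
PB14B	Pept-B-XIVb	61300	12.26	15028	3.0056	12541	2.5082
PA6A	Pept-A-VIa	29900	5.98	20876	4.1752	25392	5.0784
PB14A	Pept-B-XIVa	117674	23.5348	10624	2.1248	29702	5.9404
PA22B	Pept-A-XXIIb	98251	19.6502	42862	8.5724	17563	3.5126
PB20	Pept-B-XX	171846	34.3692	7970	1.594	3276	0.6552
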