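strain	group	peptaibol	percent
SZMC 1775	A	Pept-A-IVa	63.78
SZMC 1775	A	Pept-A-VIa	0.14
SZMC 1775	A	Pept-A-XVIa	32.13
SZMC 1775	A	Pept-A-XIXa	0.18
SZMC 1775	A	Pept-A-XXVb	0.11
SZMC 12546	A	Pept-A-IVa	47.22
SZMC 12546	A	Pept-A-VIa	0.35
SZMC 12546	A	Pept-A-XVIa	19.00
SZMC 12546	A	Pept-A-XIXa	0.41
SZMC 22614	B	Pept-B-IXa	0.38
SZMC 22614	B	Pept-B-XVI	0.47
SZMC 22614	B	Pept-B-XIVb	0.03
SZMC 22614	B	Pept-B-XX	42.26
SZMC 22614	B	Pept-B-XXVII	44.50
SZMC 22616	B	Pept-B-IXa	3.87
SZMC 22616	B	Pept-B-XIVb	0.23
SZMC 22616	B	Pept-B-XX	14.97
SZMC 22616	B	Pept-B-XXVII	21.04
SZMC 22606	B	Pept-B-XIVa	0.01
SZMC 22606	B	Pept-B-XX	9.67
SZMC 22606	B	Pept-B-XXVII	40.96
SZMC 22611	B	Pept-B-XIVa	0.05
SZMC 22611	B	Pept-B-XX	12.81
SZMC 22611	B	Pept-B-XXVII	46.88
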