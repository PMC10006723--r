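name	b13	y7p	retention_time
Pept-A-IVa	1163	774	40.21
Pept-B-IXa	1135	774	28.44
Pept-A-XVIa	1177	774	45.21
Pept-B-XVI	1149	774	31.98
Pept-A-XXVb	1191	788	49.72
Pept-B-XXVII	1163	788	37.31
Pept-A-XIXa	1177	775	46.67
Pept-B-XIVb	1149	775	31.40
Pept-A-VIa	1163	775	41.46
Pept-B-XIVa	1149	775	31.36
Pept-A-XXIIb	1191	774	48.79
Pept-B-XX	1163	774	34.41
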