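Pept-A-IVa	Ac-Aib-Ala-Aib-Ala-Aib-Ala-Gln-Aib-Vxx-Aib-Gly-Lxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Pheol
Pept-B-IXa	Ac-Aib-Ala-Aib-Ala-Aib-Ala-Gln-Aib-Vxx-Aib-Gly-Aib-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Pheol
Pept-A-XVIa	Ac-Aib-Ala-Aib-Ala-Aib-Aib-Gln-Aib-Vxx-Aib-Gly-Lxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Pheol
Pept-B-XVI	Ac-Aib-Ala-Aib-Ala-Aib-Aib-Gln-Aib-Vxx-Aib-Gly-Aib-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Pheol
Pept-A-XXVb	Ac-Aib-Ala-Aib-Ala-Aib-Aib-Gln-Aib-Lxx-Aib-Gly-Lxx-Aib-Pro-Vxx-Aib-Vxx-Gln-Gln-Pheol
Pept-B-XXVII	Ac-Aib-Ala-Aib-Ala-Aib-Aib-Gln-Aib-Lxx-Aib-Gly-Aib-Aib-Pro-Vxx-Aib-Vxx-Gln-Gln-Pheol
Pept-A-XIXa	Ac-Aib-Ala-Aib-Ala-Aib-Aib-Gln-Aib-Vxx-Aib-Gly-Lxx-Aib-Pro-Vxx-Aib-Aib-Glu-Gln-Pheol
Pept-B-XIVb	Ac-Aib-Ala-Aib-Ala-Aib-Aib-Gln-Aib-Vxx-Aib-Gly-Aib-Aib-Pro-Vxx-Aib-Aib-Glu-Gln-Pheol
Pept-A-VIa	Ac-Aib-Ala-Aib-Ala-Aib-Ala-Gln-Aib-Vxx-Aib-Gly-Lxx-Aib-Pro-Vxx-Aib-Aib-Glu-Gln-Pheol
Pept-B-XIVa	Ac-Aib-Ala-Aib-Ala-Aib-Ala-Gln-Aib-Lxx-Aib-Gly-Aib-Aib-Pro-Vxx-Aib-Aib-Glu-Gln-Pheol
Pept-A-XXIIb	Ac-Aib-Ala-Aib-Ala-Aib-Aib-Gln-Aib-Lxx-Aib-Gly-Lxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Pheol
Pept-B-XX	Ac-Aib-Ala-Aib-Ala-Aib-Aib-Gln-Aib-Lxx-Aib-Gly-Aib-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Pheol
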