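name	site
MluCI	^AATT
Tsp509I	^AATT
EcoRI	G^AATTC
DpnII	^GATC
MboI	^GATC
TaqI	T^CGA
HinfI	G^ANTC
RsaI	GT^AC
AluI	AG^CT
HaeIII	GG^CC
MseI	T^TAA
DdeI	C^TNAG
Hpy188I	TC^NGA
NlaIII	CATG^
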