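record_id	virus	group
Z46390	ALV	Alpharetrovirus
AF052428	RSV	Alpharetrovirus
M15122	MMTV	Betaretrovirus
M12349	M-PMV	Betaretrovirus
M93134	FMLV	Gammaretrovirus
M18247	FLV	Gammaretrovirus
D13784	HTLV-1	Deltaretrovirus
K02120	BLV	Deltaretrovirus
AF033822	WDSV	Epsilonretrovirus
AF133051	WEHV1	Epsilonretrovirus
M32690	BIV	Lentivirus
FIU56928	FIV	Lentivirus
M33677	CAEV	Lentivirus
M16575	EIAV	Lentivirus
AF069670	HIV-1-SE7253	Lentivirus
M30502	HIV-2-BEN	Lentivirus
JQ864086	SIV	Lentivirus
NC_001654	JDV	Lentivirus
MN531112	PLV	Lentivirus
M60609	VMV	Lentivirus
U94514	BFV	Spumaretrovirinae
Y08851	FFV	Spumaretrovirinae
U21247	SFV	Spumaretrovirinae
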