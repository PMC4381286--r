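domain	protein	group	count	motif
bacteria	GluRS	I	88	CxCx20-21Yx3C
bacteria	GluRS	II	5	CxCx20Yx3H
bacteria	GluRS	III	105	none
bacteria	GluRS	IV	7	none
bacteria	GluRS	V	7	deleted
bacteria	GluQRS	I	46	CxCx11-28Yx3C
bacteria	GluQRS	II	15	none
archaea	GluRS	I	7	CxCx14CxC
archaea	GluRS	II	16	CxCx14CxH
archaea	GluRS	III	14	none
eukarya	GluRS	I	11	CxCx20Yx3C
eukarya	GluRS	II	1	CxCx20Cx3C
eukarya	GluRS	III	10	none
eukarya	GluProRS	all	11	none
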