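term	tag	code	vocab
diabetes mellitus tipo 1	Disease	E10	ICD-10
diabetes mellitus tipo 2	Disease	E11	ICD-10
hipertensión arterial	Disease	I10	ICD-10
obesidad	Disease	E66	ICD-10
insuficiencia renal crónica	Disease	N18	ICD-10
neuropatía diabética	Disease	G63.2	ICD-10
retinopatía diabética	Disease	H36.0	ICD-10
pie diabético	Disease	E11.5	ICD-10
dislipidemia	Disease	E78	ICD-10
infección de vías urinarias	Disease	N39.0	ICD-10
gastritis	Disease	K29	ICD-10
várices	Disease	I83	ICD-10
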