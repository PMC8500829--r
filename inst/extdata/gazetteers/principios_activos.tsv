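term	tag	code	vocab
insulina glargina	API	A10AE04	ATC
insulina lispro	API	A10AB04	ATC
metformina	API	A10BA02	ATC
glibenclamida	API	A10BB01	ATC
diosmina con hesperidina	API	C05CA53	ATC
diosmina	API	C05CA03	ATC
hesperidina	API	C05CA54	ATC
enalapril	API	C09AA02	ATC
captopril	API	C09AA01	ATC
losartan	API	C09CA01	ATC
atorvastatina	API	C10AA05	ATC
bezafibrato	API	C10AB02	ATC
ácido acetilsalicílico	API	B01AC06	ATC
omeprazol	API	A02BC01	ATC
paracetamol	API	N02BE01	ATC
pregabalina	API	N03AX16	ATC
complejo b	API	A11EA	ATC
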