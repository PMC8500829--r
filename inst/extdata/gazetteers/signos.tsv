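term	tag	code	vocab
glucosa	Sign	GLU	signos
peso	Sign	PESO	signos
talla	Sign	TALLA	signos
temperatura	Sign	TEMP	signos
presión arterial	Sign	TA	signos
frecuencia cardíaca	Sign	FC	signos
cintura	Sign	CINT	signos
cadera	Sign	CAD	signos
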