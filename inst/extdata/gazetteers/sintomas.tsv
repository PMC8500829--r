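term	tag	code	vocab
poliuria	Symptom	28442001	sintomas
polidipsia	Symptom	17173007	sintomas
polifagia	Symptom	72405004	sintomas
cefalea	Symptom	25064002	sintomas
mareo	Symptom	404640003	sintomas
náuseas	Symptom	422587007	sintomas
visión borrosa	Symptom	246636008	sintomas
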