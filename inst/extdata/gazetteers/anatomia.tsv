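term	tag	code	vocab
riñón	Anatomy	64033007	anatomia
páncreas	Anatomy	15776009	anatomia
hígado	Anatomy	10200004	anatomia
miembro inferior	Anatomy	61685007	anatomia
retina	Anatomy	5665001	anatomia
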