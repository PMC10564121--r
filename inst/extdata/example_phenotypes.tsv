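individual_id	age	sex	centre	height
IND01	67	male	B	166.5
IND02	48	female	A	166.6
IND03	60	male	A	166.5
IND04	61	female	A	173.1
IND05	53	male	A	173.7
IND06	65	female	A	160.3
IND07	56	male	B	187
IND08	67	male	A	176
IND09	40	male	A	169.4
IND10	64	female	B	171.3
IND11	42	male	B	166.5
IND12	58	female	A	161.6
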