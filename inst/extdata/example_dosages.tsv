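individual_id	rs001	rs002	rs003	rs004	rs005
IND01	0	0	0	1	1
IND02	0	1	0	2	0
IND03	1	NA	0	1	1
IND04	2	1	1	2	1
IND05	0	0	0	2	1
IND06	2	0	0	1	2
IND07	1	0	0	1	0
IND08	0	0	0	2	1
IND09	0	0	0	1	0
IND10	0	0	0	2	1
IND11	0	1	0	1	1
IND12	0	1	0	1	0
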