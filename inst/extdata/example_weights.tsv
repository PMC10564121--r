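variant_id	effect_allele	beta	maf
rs001	A	0.12	0.21
rs002	C	-0.08	0.35
rs003	G	0.05	0.11
rs004	T	0.20	0.45
rs005	A	-0.15	0.28
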