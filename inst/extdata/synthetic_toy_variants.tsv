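sample	chrom	pos	ref	alt
S1	chrS	6	C	T
S1	chrS	20	C	G
S2	chrS	30	T	C
S2	chrS	42	C	T
S2	chrS	63	A	G
S2	chrS	80	G	A
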