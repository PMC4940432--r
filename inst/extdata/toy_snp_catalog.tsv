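#chrom	pos	ref	alt
1	10177	A	C
5	1295228	G	A
12	25398284	C	T
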