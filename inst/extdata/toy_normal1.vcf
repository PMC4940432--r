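##fileformat=VCFv4.2
##source=toy
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	N01
chr1	10177	.	A	C	50	PASS	.	GT:AD:DP	0/1:12,9:21
1	115252	.	G	A	50	PASS	.	GT:AD:DP	1/1:1,33:34
7	140453136	.	A	T	50	PASS	.	GT:AD:DP	0/1:20,2:22
chrX	66765	.	T	C	50	PASS	.	GT	0/1
chrM	73	.	A	G	50	PASS	.	GT:AD:DP	1/1:0,48:48
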