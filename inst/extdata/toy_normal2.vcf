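##fileformat=VCFv4.2
##source=toy
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	N02
1	10177	.	A	C	50	PASS	.	GT:AD:DP	0/1:15,11:26
1	115252	.	G	A	50	PASS	.	GT:AD:DP	0/1:18,14:32
5	1295228	.	G	A,T	50	PASS	.	GT:AD:DP	1/2:2,10,6:18
7	140453136	.	A	T	50	PASS	.	GT:AD:DP	0/1:25,3:28
X	66765	.	T	C	50	PASS	.	GT	1/1
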