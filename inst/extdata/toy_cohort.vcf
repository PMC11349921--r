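##fileformat=VCFv4.2
##reference=GRCh38
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3	S4	S5	S6
chr1	1000	.	A	T	.	PASS	.	GT	0/0	0/0	0/1	0/0	0/0	0/0
chr2	5000	.	G	C	.	PASS	.	GT	0/0	0/1	0/0	0/0	0/0	0/0
chr7	1000000	.	T	A	.	PASS	.	GT	0/0	0/0	0/0	0/1	0/0	0/0
chr7	44149764	.	G	C	.	PASS	.	GT	0/1	0/0	0/0	0/0	0/0	0/0
chr9	133071270	.	C	CC	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/1	0/0
chr11	2160956	.	G	A	.	PASS	.	GT	0/0	0/1	./.	0/0	0/0	0/0
chr12	120994313	.	C	CC	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/1
chr17	37731615	.	G	A	.	PASS	.	GT	0/1	0/0	0/0	0/0	0/0	0/0
chr17	37739468	.	G	A	.	PASS	.	GT	0/0	0/0	0/0	0/1	0/0	0/0
chr20	44413696	.	G	A	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/1	0/0
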