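##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	pool_high	pool_low
gene_x	11	s01	A	G	.	PASS	.	GT:AD	./.:3,2	./.:4,1
gene_x	25	s02	C	T	.	PASS	.	GT:AD	./.:2,1	./.:5,3
gene_x	40	s03	G	A	.	PASS	.	GT:AD	./.:96,4	./.:96,4
gene_x	55	s04	T	C	.	PASS	.	GT:AD	./.:30,10	./.:30,10
gene_x	70	s05	A	C	.	PASS	.	GT:AD	./.:20,20	./.:35,5
gene_x	85	s06	C	G	.	PASS	.	GT:AD	./.:35,5	./.:20,20
gene_x	100	s07	G	T	.	PASS	.	GT:AD	./.:30,30	./.:20,10
gene_x	115	s08	T	A	.	PASS	.	GT:AD	./.:40,0	./.:30,10
gene_x	130	s09	A	T	.	PASS	.	GT:AD	./.:30,10	./.:40,0
gene_x	145	s10	C	A	.	PASS	.	GT:AD	./.:0,0	./.:0,0
gene_x	160	s11	G	C	.	PASS	.	GT:AD	./.:10,10	./.:30,10
gene_x	175	s12	T	G	.	PASS	.	GT:AD	./.:30,10	./.:10,10
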