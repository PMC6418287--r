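##fileformat=VCFv4.2
##source=cnaphase
##contig=<ID=1,length=10000000>
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	N	T1R1
1	1000	.	A	G	.	.	.	DP:AD	50:50,0	100:70,30
1	2000	.	C	T	.	.	.	DP:AD	50:48,2	100:70,30
1	3000	.	G	A	.	.	.	DP:AD	9:9,0	100:70,30
1	4000	.	T	C	.	.	.	DP:AD	50:50,0	7:4,3
1	5000	.	A	C	.	.	.	DP:AD	50:50,0	40:38,2
1	6000	.	G	T	.	.	.	DP:AD	50:50,0	100:70,30
1	7000	.	C	G	.	.	.	DP:AD	50:50,0	100:70,30
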