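# Allele-specific primer pairs of the seven three-primer genotyping assays
# used on the bundled PCOS cohort. Alleles are given on the primer strand
# (for reverse-orientation primers that is the complement of the reported
# SNP allele). Sequences 5'->3'.
rsid	gene	method	orientation	wild_allele	mut_allele	wild_primer	mutant_primer	common_primer
rs9939609	FTO	HRM	forward	T	A	TAGGCTCCTCGCGACTGCTGTGAATATT	TATGTTCATTGCGACTGCTGTGAATATA	GAGTAACAGAGACTATCCAAGTGCATCAC
rs6169	FSHB	HRM	reverse	G	A	CGGGCACTCTCACTGTTCCG	CAGGCACTCTCACTGTTACA	GTACCTTCAAGGAACTGGTAT
rs6165	FSHR	HRM	forward	T	C	CAGAGAGAATCTCTGAACCCTAGT	CAGAGAGGGTCTCTGAGCCCTAGC	GGCAAGAAGTTGATTATATGACTCAG
rs6166	FSHR	HRM	forward	T	C	AGGGACAAGTATGTAAGTAGAACCAT	AGGGACAAGTATGTGAGTGGAACCAC	CTCTTCAGCTCCCAGAGTCACCA
rs1799817	INSR	HRM	reverse	C	T	TCGGTCATGAAGGGCTTCACCTGCCATGAC	TAAGTCATGAAGGGCTTCACCTGCCATAAT	ATGTCCCACCCCCACTGGACTCACAAC
rs6185	GNRH1	AS-qPCR	reverse	G	C	CGCCTAGCTGGCCTTATTCTACTGACGTG	CTACTAGCTGGCCTTATTCTACTGACATC	TGGCTGGAGCAGCCTTCCACTCA
rs1800447	LHB	AS-qPCR	forward	A	G	ATTGCATTGATGGGGTGGCAACA	ATGGCATTGATGGGGTGGCAGCG	ATCCAGGGAGCCGCTTCGGACA
rs34349826	LHB	AS-qPCR	reverse	T	C	CTATGGTGCCACCCCATCAATGCAAT	CCGTGGTGCCACCCCATCAATGCAAC	AGCCCTCCTTCTCGACAGCCTGG
rs2293275	LHCGR	AS-qPCR	forward	T	C	GTATGCAAATACTTACAGTGTTTTGTGAT	AGCCGGCAAATACTTACAGTGTTTTGTGAC	CAATGTGAAAGCACAGTAAGGAAAGTGA
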