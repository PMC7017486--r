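##fileformat=VCFv4.2
##source=graphsv
##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">
##INFO=<ID=END,Number=1,Type=Integer,Description="End position of the variant">
##INFO=<ID=SVLEN,Number=.,Type=Integer,Description="Length of the variant">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth (site support)">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic read support">
##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s1
chrF	1200	mini_del	TTAATCCACGGATGTGCGGCAGAATTACAGTGCTCCTAGAGGGAAAGCCGATCGGACTTTTAGTAGAAGAGTGGTTATTCAACAGGTTTAAGCATTCGCCGGCAGACTATTGTTCGGTTTTCTTACGGAGGTGTGCGTTGGCGCTTCCTTGGATGAGTACATCAGCAAGCGACTTGAGAACCATGCTGGTTGTGCCGGACCGATCATGGGTCTCTGCTCGAGAGATGACCTTATTCAATCGGGCAACACCGATTGCGTTTGGAACGAAAGCTCCCGGTCACATGAACATCCATACTGATAC	T	.	.	SVTYPE=DEL;END=1500;SVLEN=-300	GT	0|1
chrF	2800	mini_ins	A	ATCGACAAGATTGGGGGTTTCTTATGATGCTTACCACAGCGCCTATCCTCCCACCCCGCGCTCTAGACTATCCTGTGCGAAAGCGGTCACTCTAGCTTTTTAAGGGCTGGTATGATGAGTTGAAAAGGTTAGCTGCACGTGGTCTCCACACGGGCTGGGGTGATTCAGAGGCGCATCCGTA	.	.	SVTYPE=INS;END=2800;SVLEN=180	GT	1|1
chrF	4200	mini_inv	AGGCACGAGAAATTGAGTCTTGCATTTTGCGTCCCTAACAAGCAACTTGCAGTGCACTGGGTTCTCTTCGACAACTCCCACGTACACACGAGCACCGCCCAAGAGGCTATCTCCCCGTACGCCATAACGCCAGCGTCAGGTATGGGTGCACCCTATATAGCCATTTGTATTGGGTAAGTACACTCTGAACAGCATCTTCTGGGGCGCAGCACACCTGCATCGGACACGCTCTGTTAGCGGCCGTTGAAATC	AGATTTCAACGGCCGCTAACAGAGCGTGTCCGATGCAGGTGTGCTGCGCCCCAGAAGATGCTGTTCAGAGTGTACTTACCCAATACAAATGGCTATATAGGGTGCACCCATACCTGACGCTGGCGTTATGGCGTACGGGGAGATAGCCTCTTGGGCGGTGCTCGTGTGTACGTGGGAGTTGTCGAAGAGAACCCAGTGCACTGCAAGTTGCTTGTTAGGGACGCAAAATGCAAGACTCAATTTCTCGTGCC	.	.	SVTYPE=INV;END=4450;SVLEN=250	GT	0|1
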