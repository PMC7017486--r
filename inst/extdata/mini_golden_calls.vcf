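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
chrF	1200	mini_del	TTAATCCACGGATGTGCGGCAGAATTACAGTGCTCCTAGAGGGAAAGCCGATCGGACTTTTAGTAGAAGAGTGGTTATTCAACAGGTTTAAGCATTCGCCGGCAGACTATTGTTCGGTTTTCTTACGGAGGTGTGCGTTGGCGCTTCCTTGGATGAGTACATCAGCAAGCGACTTGAGAACCATGCTGGTTGTGCCGGACCGATCATGGGTCTCTGCTCGAGAGATGACCTTATTCAATCGGGCAACACCGATTGCGTTTGGAACGAAAGCTCCCGGTCACATGAACATCCATACTGATAC	T	6	.	SVTYPE=DEL;END=1500;SVLEN=-300	GT:DP:AD:GQ	0/1:13:8,5:6
chrF	2800	mini_ins	A	ATCGACAAGATTGGGGGTTTCTTATGATGCTTACCACAGCGCCTATCCTCCCACCCCGCGCTCTAGACTATCCTGTGCGAAAGCGGTCACTCTAGCTTTTTAAGGGCTGGTATGATGAGTTGAAAAGGTTAGCTGCACGTGGTCTCCACACGGGCTGGGGTGATTCAGAGGCGCATCCGTA	12	.	SVTYPE=INS;END=2800;SVLEN=180	GT:DP:AD:GQ	1/1:15:0,15:12
chrF	4200	mini_inv	AGGCACGAGAAATTGAGTCTTGCATTTTGCGTCCCTAACAAGCAACTTGCAGTGCACTGGGTTCTCTTCGACAACTCCCACGTACACACGAGCACCGCCCAAGAGGCTATCTCCCCGTACGCCATAACGCCAGCGTCAGGTATGGGTGCACCCTATATAGCCATTTGTATTGGGTAAGTACACTCTGAACAGCATCTTCTGGGGCGCAGCACACCTGCATCGGACACGCTCTGTTAGCGGCCGTTGAAATC	AGATTTCAACGGCCGCTAACAGAGCGTGTCCGATGCAGGTGTGCTGCGCCCCAGAAGATGCTGTTCAGAGTGTACTTACCCAATACAAATGGCTATATAGGGTGCACCCATACCTGACGCTGGCGTTATGGCGTACGGGGAGATAGCCTCTTGGGCGGTGCTCGTGTGTACGTGGGAGTTGTCGAAGAGAACCCAGTGCACTGCAAGTTGCTTGTTAGGGACGCAAAATGCAAGACTCAATTTCTCGTGCC	5	.	SVTYPE=INV;END=4450;SVLEN=250	GT:DP:AD:GQ	0/1:13:6,7:5
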