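# Viral genomes by family and source dataset, as printed in a deeply
# sequenced three-dataset (metagenome / metavirome / metatranscriptome)
# gut-virome survey. Printed column totals: 1499 / 330 / 342 (grand total
# 2171); note the body rows do not sum exactly to the printed totals and the
# Caudovirales rows sum to 1887 while the survey text states n = 1892.
family	group	metavirome_only	metagenome_only	both
Myoviridae	Caudovirales	148	65	48
Podoviridae	Caudovirales	37	5	12
Siphoviridae	Caudovirales	910	214	242
Unassigned Caudovirales	Caudovirales	138	45	23
Anelloviridae	Other	6	0	0
Circoviridae	Other	86	0	0
Cruciviridae	Other	5	0	0
Geminiviridae	Other	2	0	0
Genomoviridae	Other	1	0	0
Inoviridae	Other	1	1	0
Microviridae	Other	50	0	3
Mimiviridae	Other	0	1	0
Nanoviridae	Other	1	0	0
Phycodnaviridae	Other	3	1	0
Unassigned viruses	Other	109	9	2
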