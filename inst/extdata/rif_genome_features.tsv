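species	group	scaffolds	n50_bp	genome_size_bp	protein_count	busco_pct	gc_pct
Anthracina ramose	RIF	23	2,213,505	28,023,014	10,000	96.5	49.39
Bradymyces pullus	RIF	55	3,530,694	29,490,499	11,185	97.3	49.59
Catenulostroma hermanusense	RIF	53	1,008,637	27,547,763	11,761	98.7	53.18
Lapidomyces sp.	RIF	13	2,018,184	24,604,082	10,549	98.9	52.42
Lithophila catenulate	RIF	42	4,257,975	28,020,065	11,457	97.3	50.06
Rachicladosporium sp.	RIF	52	1,453,977	24,600,606	10,933	97.7	55.64
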