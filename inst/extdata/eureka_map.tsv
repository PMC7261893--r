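locus	lg	cm	class	p1_a1	p1_a2	p2_a1	p2_a2
CIBE6126	1	2.68	SSR	218	220	NA	NA
CIBE6147	1	14.39	SSR	214	293	NA	NA
CiC4827-01	1	20.54	SNP	A	G	NA	NA
1P3705568	1	32.48	SNP	A	G	NA	NA
EMA-M30	1	46.03	SNP	C	T	NA	NA
mCrCIR06B05	1	50.27	SSR	187	199	NA	NA
CIBE5720	1	58.15	SSR	320	333	NA	NA
MEST539	1	61.82	SSR	97	104	NA	NA
MEST001	1	70.60	SSR	171	187	NA	NA
CIC5950-02	1	91.37	SNP	G	A	NA	NA
TSC-C80	1	111.55	SNP	T	G	NA	NA
MEST431	1	119.00	SSR	331	348	NA	NA
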