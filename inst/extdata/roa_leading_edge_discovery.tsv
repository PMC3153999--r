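snp_id	gene	p_value	role	alleles	maf
rs7037147	IFNA14	1.10e-3	Intron	A/G	0.16
rs6883910	ATG12	2.11e-3	Upstream	A/C	0.39
rs7852323	IFNA21	2.90e-3	Upstream	A/G	0.17
rs1360286	IFNA5	3.16e-3	Downstream	A/C	0.21
rs10964938	IFNA17	3.49e-3	Upstream	A/C	0.18
rs10757219	IFNA8	4.92e-3	Promoter/regulatory region	A/G	0.28
rs2015345	IFNA16	5.46e-3	Downstream	A/C	0.17
rs1477479	IFNA4	6.02e-3	Downstream	A/T	0.17
rs7856345	IFNA7	6.55e-3	Downstream	A/T	0.18
rs17536147	ATG7	8.32e-3	Intron	C/G	0.08
rs637949	IFNA13	1.21e-2	Upstream	C/G	0.17
rs9955346	PIK3C3	1.57e-2	Upstream	A/G	0.17
rs694433	ATG5	1.62e-2	Upstream	A/G	0.21
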