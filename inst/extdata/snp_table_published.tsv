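snp_id	replicon	pos	ref	alt	gene_id	mt	aa_change	gene_name	process	product
SNP01	chromosome	63020	C	A	Gene0056	N	Q86H	HP	NA	Transposase
SNP10	chromosome	695080	T	C	Gene0658	N	S194P	hcaR	Transcription regulation	Transcriptional activator for 3-phenylpropionic acid catabolism
SNP22	chromosome	1283071	A	G	Gene1205	N	L186S	HP	NA	Hypothetical protein
SNP23	chromosome	1338981	A	C	Gene1257	N	D484E	ram2	Protein farnesylation	Bacterial alpha-L-rhamnosidase 6 hairpin glycosidase
SNP27	chromosome	1589637	G	T	Gene1470	N	L827M	trePP	Carbohydrate metabolic process	Trehalose 6-phosphate phosphorylase
SNP28	chromosome	1590767	T	G	Gene1470	N	D450A	trePP	Carbohydrate metabolic process	Trehalose 6-phosphate phosphorylase
SNP32	chromosome	1861048	T	C	Gene1717	S	T164T	yagU	Response to acidic pH	Inner membrane protein response to acidic
SNP41	chromosome	2799363	A	G	Gene2601	S	E328E	spa	Virulence	Immunoglobulin G-binding protein
SNP43	chromosome	2854610	A	C	Gene2651	N	D202A	gor	Glutathione metabolic process	Glutathione reductase
SNP47	chromosome	3007289	T	G	Gene2804	S	A96A	int4	DNA integration	Transposase
SNP46	chromosome	3007122	T	G	Gene2804	N	S41A	int4	DNA integration	Transposase
SNP50	chromosome	3212834	T	G	Gene3003	N	F99L	ybhF	Transport	ABC transporter ATP-binding protein
SNP51	chromosome	3213000	G	T	Gene3003	N	V155L	ybhF	Transport	ABC transporter ATP-binding protein
SNP55	chromosome	3310964	C	T	Gene3110	N	G130S	tnp2PF3	Transposition	Transposase
SNP56	chromosome	3311024	T	C	Gene3110	N	T110A	tnp2PF3	Transposition	Transposase
SNP57	chromosome	3311155	A	C	Gene3110	N	V66G	tnp2PF3	Transposition	Transposase
SNP58	chromosome	3311174	T	C	Gene3110	N	N60D	tnp2PF3	Transposition	Transposase
SNP60	chromosome	3311545	T	C	Gene3111	N	K35E	tnp2PF3	Transposition	Transposase
SNP59	chromosome	3311468	G	A	Gene3111	S	S60S	tnp2PF3	Transposition	Transposase
SNP61	chromosome	1976363	A	G	NA	NA	NA	NA	NA	NA
SNP62	chromosome	1976367	G	T	NA	NA	NA	NA	NA	NA
SNP71	chromosome	3271378	G	T	NA	NA	NA	NA	NA	NA
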