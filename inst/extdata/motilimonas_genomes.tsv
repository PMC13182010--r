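genome_id	label	accession	assembly_level	size_mb	cds	n_transporter_genes	abc_sugar_genes	pts_sugar_genes
Spo1_1	Motilimonas sp. Spo1_1	GCA_051055415.1	chromosome	4.8	4257	280	16	11
E26	Motilimonas sp. E26	GCA_021278025.1	scaffold	4.6	4181	282	16	11
G1M02	Motilimonas sp. 1_MG-2023 G1M02	GCA_030547455.1	contig	4.8	4290	289	18	15
MKS20	Motilimonas cestriensis MKS20	GCA_021295315.1	scaffold	4.8	4325	294	21	20
YH6	Motilimonas eburnea YH6	GCA_021295345.1	scaffold	4.6	4137	263	9	10
KMU-193	Motilimonas sp. KMU-193	GCA_046452435.1	contig	4.2	3751	268	12	10
PLHSC7-2	Motilimonas pumila PLHSC7-2	GCA_003596335.1	contig	4.5	4047	256	9	10
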