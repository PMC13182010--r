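## example eggNOG-mapper style annotations (synthetic fixture)
#query	COG_category	eggNOG_OGs	KEGG_ko	Description
gene1	G	COG1263@1|root,COG1264@2|Bacteria	ko:K02777,ko:K02778	PTS glucose transporter subunit
gene2	GT	COG0642@1|root	ko:K03407	sensor histidine kinase
gene3	-	-	-	hypothetical protein
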