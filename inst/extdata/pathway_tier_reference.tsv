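pathway	super_class	hit_count	pathway_p	enrichment_p	impact	kegg_ids	lcgcms_trend	mr_trend	sig_lcgcms	sig_wgcna	sig_mr	pool_enriched	expected_tier
Glycine, serine and threonine metabolism	Amino Acid Metabolism	8	0.005	0.005	0.29	C00065,C00114,C02291,C01005,C00258,C00097,C03508,C00022	up	down	TRUE	TRUE	TRUE	TRUE	I
Cysteine and methionine metabolism	Amino Acid Metabolism	5	0.005	0.005	0.30	C02291,C00065,C00097,C01005,C00022	up	down	TRUE	FALSE	TRUE	TRUE	I
Alanine, aspartate and glutamate metabolism	Amino Acid Metabolism	4	0.005	0.005	0.20	C00041,C00025,C00022,C00042	down	down	FALSE	FALSE	TRUE	TRUE	II
Glycerophospholipid metabolism	Lipid Metabolism	4	0.01	0.14	0.22	C00157,C04230,C00114,C00093	down	down	TRUE	FALSE	TRUE	TRUE	II
Purine metabolism	Nucleotide Metabolism	4	0.01	0.005	0.21	C00385,C00020,C00130,C00387	up	absent	TRUE	TRUE	FALSE	TRUE	II
Glutathione metabolism	Amino Acid Metabolism	4	0.005	0.005	0.04	C00097,C00025,C01879,C00315	up	up	FALSE	FALSE	TRUE	TRUE	III
One carbon pool by folate	Vitamin and Cofactor Metabolism	4	0.005	0.15	0.06	C00114,C00065,C02291,C00097	up	down	TRUE	FALSE	FALSE	TRUE	III
Butanoate metabolism	Carbohydrate Metabolism	2	0.05	0.04	0	C00025,C00042	down	up	FALSE	TRUE	FALSE	FALSE	III
Sphingolipid metabolism	Lipid Metabolism	4	0.005	0.005	0.06	C06124,C00319,C00065,C12144	down	absent	TRUE	FALSE	FALSE	TRUE	III
Arginine and proline metabolism	Amino Acid Metabolism	3	0.005	0.005	0.07	C00315,C00025,C00022	absent	up	FALSE	FALSE	TRUE	TRUE	III
alpha-Linolenic acid metabolism	Lipid Metabolism	2	0.01	0.03	0.33	C00157,C06427	mixed	absent	TRUE	FALSE	FALSE	FALSE	III*
Glyoxylate and dicarboxylate metabolism	Carbohydrate Metabolism	4	0.005	0.005	0.09	C02557,C00065,C00025,C00258,C00022	up	mixed	TRUE	FALSE	TRUE	TRUE	III*
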