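# Curated subset of well-known assay-interference (PAINS-family) motifs, v1.
# Columns: id<TAB>smarts. The interference filter accepts any table with
# this layout, so a campaign can substitute its own full pattern set.
id	smarts
quinone_A	O=C1C=CC(=O)C=C1
ortho_quinone	O=C1C=CC(=O)c2ccccc12
catechol	[OX2H]c1ccccc1[OX2H]
rhodanine	O=C1CSC(=S)N1
ene_rhodanine	O=C1C(=C)SC(=S)N1
hydrazone_aryl	c[CX3]=[NX2][NX3]
azo_aryl	cN=Nc
alkylidene_barbiturate	O=C1NC(=O)NC(=O)C1=[CX3]
isothiazolone	O=C1C=CSN1
thiourea	[NX3][CX3](=S)[NX3]
beta_keto_1_3	[CX3](=O)[CH2][CX3](=O)
nitroso	[NX2]=[OX1]
mannich_phenol	[OX2H]c1ccccc1C[NX3]
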