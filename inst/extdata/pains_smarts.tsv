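# Pinned PAINS substructure catalog (plain-SMARTS subset of the published
# pan-assay interference families A/B/C, limited to patterns OpenBabel
# parses). Version: pcmcp-1; do not edit without bumping tests.
name	smarts
quinone_para	O=C1C=CC(=O)C=C1
quinone_ortho	O=C1C(=O)C=CC=C1
azo_aromatic	cN=Nc
phenyl_hydrazone	c1ccccc1C=N[NX3]
rhodanine	O=C1CSC(=S)N1
ene_rhodanine	O=C1C(=[CX3])SC(=S)N1
thiourea	[NX3][CX3](=S)[NX3]
isothiazolone	O=c1ccs[nX3]1
alkylidene_barbiturate	O=C1NC(=O)NC(=O)C1=[CX3]
sulfonyl_hydrazide	S(=O)(=O)N[NX3]
acyl_hydrazone	O=CN[NX2]=C
nitroso	[c,CX4][NX2]=O
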