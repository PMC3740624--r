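code	combining	full_names	formula	smiles_template
ala	alanyl	alanine	C3H7NO2	NC(C)C(=O)
arg	arginyl	arginine	C6H14N4O2	NC(CCCNC(N)=N)C(=O)
asn	asparaginyl	asparagine	C4H8N2O3	NC(CC(N)=O)C(=O)
asp	aspartyl	aspartate|aspartic acid	C4H7NO4	NC(CC(O)=O)C(=O)
cys	cysteinyl	cysteine	C3H7NO2S	NC(CS)C(=O)
gln	glutaminyl	glutamine	C5H10N2O3	NC(CCC(N)=O)C(=O)
glu	glutamyl	glutamate|glutamic acid	C5H9NO4	NC(CCC(O)=O)C(=O)
gly	glycyl	glycine	C2H5NO2	NCC(=O)
his	histidyl	histidine	C6H9N3O2	NC(Cc1c[nH]cn1)C(=O)
ile	isoleucyl	isoleucine	C6H13NO2	NC(C(C)CC)C(=O)
leu	leucyl	leucine	C6H13NO2	NC(CC(C)C)C(=O)
lys	lysyl	lysine	C6H14N2O2	NC(CCCCN)C(=O)
met	methionyl	methionine	C5H11NO2S	NC(CCSC)C(=O)
phe	phenylalanyl	phenylalanine	C9H11NO2	NC(Cc1ccccc1)C(=O)
pro	prolyl	proline	C5H9NO2	N1CCCC1C(=O)
ser	seryl	serine	C3H7NO3	NC(CO)C(=O)
thr	threonyl	threonine	C4H9NO3	NC(C(C)O)C(=O)
trp	tryptophyl	tryptophan	C11H12N2O2	NC(Cc1c[nH]c2ccccc12)C(=O)
tyr	tyrosyl	tyrosine	C9H11NO3	NC(Cc1ccc(O)cc1)C(=O)
val	valyl	valine	C5H11NO2	NC(C(C)C)C(=O)
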