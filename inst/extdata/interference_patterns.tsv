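# Pan-assay interference (PAINS-style) substructure subset.
# name<TAB>SMARTS
quinone_para	O=C1C=CC(=O)C=C1
quinone_ortho	O=C1C(=O)C=CC=C1
catechol	Oc1ccccc1O
rhodanine	S=C1NC(=O)CS1
ene_rhodanine	S=C1NC(=O)C(=C)S1
hydroxyphenyl_hydrazone	Oc1ccccc1C=NN
azo_aryl	cN=Nc
aryl_nitroso	cN=O
isothiazolone	O=C1C=CSN1
mannich_phenol	OC1=CC=CC=C1CN(C)C
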