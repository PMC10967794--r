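# Reactive / assay-hostile structural alert subset (demerit-style rules
# without scoring; documented stand-in for a full medicinal-chemistry rule
# program).
# name<TAB>SMARTS
acyl_halide	C(=O)[Cl,Br,I]
aldehyde	[CX3H1]=O
epoxide	C1OC1
aziridine	C1NC1
anhydride	C(=O)OC(=O)
azide	N=[N+]=[N-]
peroxide	[OX2][OX2]
michael_acceptor	[CX3]=[CX3][CX3]=[OX1]
isocyanate	N=C=O
thiourea	NC(=S)N
alpha_halo_ketone	C(=O)C[Cl,Br,I]
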