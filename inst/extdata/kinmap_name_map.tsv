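uniprot	kinase_name
P00533	EGFR
P35968	KDR
P09619	PDGFRB
P00519	ABL1
O75116	ROCK2
Q96GD4	AURKB
P07949	RET
P36897	TGFBR1
O43353	RIPK2
O14757	CHEK1
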