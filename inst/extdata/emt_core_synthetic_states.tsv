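node	epithelial	mesenchymal
TGFb	0	0
TGFbR	0	0
SMAD	0	0
RAS	0	1
MEK	0	1
SNAI1	0	1
ZEB	0	1
miR200	1	0
Ecadherin	1	0
EMT	0	1
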