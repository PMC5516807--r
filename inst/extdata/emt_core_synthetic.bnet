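# Synthetic core EMT-like signalling network (authored for this package as a
# compact demonstration model; not transcribed from any published model).
# TGFb signals through a canonical (SMAD) and a non-canonical (RAS/MEK) arm
# that converge on E-cadherin-repressing transcription factors; miR200 and
# ZEB form a mutual-inhibition switch; the EMT readout reports E-cadherin loss.
targets, factors
TGFb, TGFb
TGFbR, TGFb
SMAD, TGFbR
RAS, TGFbR | SNAI1
MEK, RAS
SNAI1, SMAD | MEK
ZEB, SNAI1 & !miR200
miR200, !SNAI1 & !ZEB
Ecadherin, !ZEB
EMT, !Ecadherin
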