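# Bracket-class motifs recovered from quorum-sensing peptide sets
# (pattern notation: literal residues and [..] alternative classes).
# Format: id<TAB>expression
Motif 1	LSTFFRLFNRSFTQA
Motif 2	[YP][NS][PTI][CF]GQ[YW][MF]
Motif 3	[TA]S[NS][IL][SV][KE]CVFS[FL]FKKC
Motif 4	E[SM]R[LI][SP][KR]I[LI][LR]DF
Motif 5	[DE]I[IL]IIVGG
Motif 6	LPYF[AF][GK][CH]L
Motif 7	[DS]SAC[VY][VW][GC]
Motif 8	G[LW]WE[DE][LI]L[YH]
Motif 9	DPITRQW
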