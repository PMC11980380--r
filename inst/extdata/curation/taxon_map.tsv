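transcriptId	cellId	geneFamilyId
A1	cellA	gf1
A2	cellA	gf1
A3	cellA	gf1
B1	cellB	gf1
B2	cellB	gf1
B3	cellB	gf1
C1	cellC	gf2
C2	cellD	gf2
C3	cellC	gf2
C4	cellC	gf2
D1	cellE	gf3
D2	cellE	gf3
E1	cellF	gf4
E2	cellG	gf4
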