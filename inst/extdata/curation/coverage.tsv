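transcriptId	kmerCoverage	readCount
A1	50	500
A2	8	40
A3	10	60
B1	60	800
B2	5	20
B3	15	90
C1	40	400
C2	30	350
C3	20	30
C4	25	80
D1	70	900
D2	40	300
E1	30	200
E2	40	450
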