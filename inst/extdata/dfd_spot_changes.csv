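# Reference fold-change (FC) and relative-change (RC) values for the same 32
# significantly changed spots as dfd_spot_summary.csv, as published. FC uses
# the negative-reciprocal convention for ratios below one; group-unique
# spots have infinite FC, serialized as +inf / -inf. RC = DPR/|DPR_max| with
# DPR_max taken over these 32 spots.
spot_id,protein,fc,rc
1,PGM1 (1),+inf,0.44
5,PGM1 (2),-4.50,-0.30
6,UQCRC1,-inf,-0.13
7,ENO3 (1),+inf,0.57
8,ENO3 (2),+inf,0.51
9,ENO3 (3),+inf,0.38
10,ACTA1 (1),+inf,0.35
11,ACTA1 (2),+inf,0.33
15,CKM (1),+inf,0.37
16,CKM (2),+inf,0.32
18,ACTA1 (3),-inf,-0.13
19,ACTA1 (4),-inf,-0.16
20,ACTA1 (5),-inf,-0.14
21,ACTA1 (6),-inf,-0.12
22,TNNT3 (1),+inf,0.74
23,TNNT3 (2),+inf,0.73
24,TNNT3 (3),+inf,0.70
25,TNNT3 (4),+inf,0.67
26,CAPZA2,+inf,0.77
27,ACTA1 (7),-inf,-0.39
30,TNNT1 (1),-inf,-0.78
30A,TNNT1 (2),+inf,0.76
33,HSPB1 (1),-inf,-0.52
34,HSPB1 (2),+inf,0.73
37,HSPB1 (3),+inf,0.69
44,MYL6B (1),-inf,-0.49
46,MYL6B (2),-inf,-0.14
50,HSPB6,-inf,-0.10
51,MYL2 (1),-inf,-0.40
52,MYL2 (2),-inf,-0.39
53,MYLPF (1),+inf,0.99
54,MYLPF (2),+inf,1.00
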