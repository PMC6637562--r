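# Reference per-spot phosphorylation-rate summary from a published bovine
# DFD (dark, firm, dry) vs control meat phosphoproteome case study:
# 32 spots with significant differential phosphorylation; group-mean PR,
# standard error, and Bonferroni-adjusted 95% BC-percentile bootstrap CI
# bounds (N = 4 biological replicates per group). Zero means have no CI.
spot_id,protein,pr_mean_treated,se_treated,ci_lower_treated,ci_upper_treated,pr_mean_control,se_control,ci_lower_control,ci_upper_control
1,PGM1 (1),0.41,0.10,0.292,0.603,0,NA,NA,NA
5,PGM1 (2),0.08,0.03,0.051,0.108,0.36,0.12,0.169,0.696
6,UQCRC1,0,NA,NA,NA,0.12,0.06,0.060,0.171
7,ENO3 (1),0.54,0.21,0.206,0.939,0,NA,NA,NA
8,ENO3 (2),0.48,0.08,0.281,0.614,0,NA,NA,NA
9,ENO3 (3),0.36,0.10,0.153,0.630,0,NA,NA,NA
10,ACTA1 (1),0.33,0.06,0.205,0.435,0,NA,NA,NA
11,ACTA1 (2),0.31,0.03,0.238,0.371,0,NA,NA,NA
15,CKM (1),0.35,0.16,0.154,0.655,0,NA,NA,NA
16,CKM (2),0.31,0.04,0.237,0.379,0,NA,NA,NA
18,ACTA1 (3),0,NA,NA,NA,0.12,0.04,0.067,0.186
19,ACTA1 (4),0,NA,NA,NA,0.15,0.05,0.041,0.206
20,ACTA1 (5),0,NA,NA,NA,0.13,0.02,0.105,0.179
21,ACTA1 (6),0,NA,NA,NA,0.11,0.05,0.031,0.187
22,TNNT3 (1),0.70,0.12,0.458,0.948,0,NA,NA,NA
23,TNNT3 (2),0.69,0.08,0.505,0.874,0,NA,NA,NA
24,TNNT3 (3),0.66,0.10,0.452,0.804,0,NA,NA,NA
25,TNNT3 (4),0.63,0.06,0.447,0.693,0,NA,NA,NA
26,CAPZA2,0.72,0.19,0.531,0.904,0,NA,NA,NA
27,ACTA1 (7),0,NA,NA,NA,0.37,0.19,0.175,0.563
30,TNNT1 (1),0,NA,NA,NA,0.73,0.19,0.358,0.929
30A,TNNT1 (2),0.71,0.15,0.402,0.879,0,NA,NA,NA
33,HSPB1 (1),0,NA,NA,NA,0.49,0.24,0.033,0.839
34,HSPB1 (2),0.69,0.25,0.192,0.951,0,NA,NA,NA
37,HSPB1 (3),0.65,0.19,0.467,0.835,0,NA,NA,NA
44,MYL6B (1),0,NA,NA,NA,0.46,0.20,0.087,0.776
46,MYL6B (2),0,NA,NA,NA,0.13,0.03,0.073,0.177
50,HSPB6,0,NA,NA,NA,0.09,0.05,0.011,0.194
51,MYL2 (1),0,NA,NA,NA,0.38,0.14,0.211,0.664
52,MYL2 (2),0,NA,NA,NA,0.37,0.19,0.020,0.764
53,MYLPF (1),0.93,0.05,0.831,1.000,0,NA,NA,NA
54,MYLPF (2),0.94,0.04,0.875,1.000,0,NA,NA,NA
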