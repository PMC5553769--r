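gene_id	d1	d2
A1BG	3.34	-3.63
ANKRD39	3.93	-3.35
CA4	-4.4	4.94
CDK14	-4.88	3.34
CHCHD2	3.5	-3.65
CXCR2	-4.67	3.38
HCG27	-4.68	3.29
KAT6A	-3.48	3.54
MFSD3	4.25	-3.29
MMP9	-3.51	5.77
MRPL14	4.06	-3.69
MRPL15	3.99	-3.38
MRPL55	3.63	-3.95
NDUFB7	3.79	-3.54
NDUFS3	3.98	-3.89
PRPS1	3.87	-4.13
RBBP6	3.66	-3.67
ROMO1	3.33	-3.41
SEPHS1	4	-3.44
TANC2	-3.59	3.95
TCN1	-4.69	3.36
TMEM141	3.45	-3.64
TRIM33	-4.64	3.47
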