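gene_id	d1	d2
CA4	-4.4	4.94
CDK14	-4.88	3.34
CXCR2	-4.67	3.38
HCG27	-4.68	3.29
MME	-6.05	3.25
TCN1	-4.69	3.36
TRIM33	-4.64	3.47
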