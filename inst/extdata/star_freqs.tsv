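# European-population star-allele frequencies for the haplotype-level genes. The *1
# (reference) frequency is the complement of the listed alleles and is added on load.
# Alleles printed as <0.01% in the source are carried at frequency 0.
gene	allele	freq
SLCO1B1	*5	0.000
SLCO1B1	*15	0.150
SLCO1B1	*37	0.253
UGT1A1	*80	0.314
CYP2D6	*3	0.016
CYP2D6	*4	0.185
CYP2D6	*6	0.011
CYP2D6	*7	0.000
CYP2D6	*8	0.000
CYP2D6	*9	0.028
CYP2D6	*10	0.016
CYP2D6	*14	0.000
CYP2D6	*17	0.004
CYP2D6	*41	0.092
CYP2A6	*9	0.071
CYP2B6	*4	0.409
CYP2B6	*5	0.116
CYP2B6	*6	0.233
CYP2B6	*7	0.025
CYP2B6	*9	0.015
CYP2C8	*2	0.004
CYP2C8	*3	0.118
CYP2C8	*4	0.058
CYP2C9	*2	0.127
CYP2C9	*3	0.076
CYP2C19	*2	0.147
CYP2C19	*3	0.002
CYP2C19	*4	0.002
CYP2C19	*17	0.215
CYP3A4	*2	0.000
CYP3A4	*6	0.000
CYP3A4	*20	0.001
CYP3A4	*22	0.037
CYP3A5	*3	0.924
CYP3A5	*6	0.000
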