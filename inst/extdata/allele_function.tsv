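# Star-allele function assignments bundled as a versioned fixture (2023-08 CPIC/DPWG-style
# gene-specific conventions; PharmVar-style allele definitions). activity is the numeric
# per-allele value used for activity-score genes (CYP2D6, CYP2C9); function_class is used
# for the class-combination genes. CYP2C8 assignments are provisional (no consensus table).
gene	allele	activity	function_class
SLCO1B1	*1	NA	normal
SLCO1B1	*5	NA	decreased
SLCO1B1	*15	NA	decreased
SLCO1B1	*37	NA	normal
UGT1A1	*1	NA	normal
UGT1A1	*80	NA	decreased
CYP2D6	*1	1	normal
CYP2D6	*3	0	no
CYP2D6	*4	0	no
CYP2D6	*5	0	no
CYP2D6	*6	0	no
CYP2D6	*7	0	no
CYP2D6	*8	0	no
CYP2D6	*9	0.25	decreased
CYP2D6	*10	0.25	decreased
CYP2D6	*14	0	no
CYP2D6	*17	0.5	decreased
CYP2D6	*41	0.25	decreased
CYP2A6	*1	NA	normal
CYP2A6	*9	NA	decreased
CYP2B6	*1	NA	normal
CYP2B6	*4	NA	increased
CYP2B6	*5	NA	normal
CYP2B6	*6	NA	decreased
CYP2B6	*7	NA	decreased
CYP2B6	*9	NA	decreased
CYP2C8	*1	NA	normal
CYP2C8	*2	NA	decreased
CYP2C8	*3	NA	decreased
CYP2C8	*4	NA	decreased
CYP2C9	*1	1	normal
CYP2C9	*2	0.5	decreased
CYP2C9	*3	0	no
CYP2C19	*1	NA	normal
CYP2C19	*2	NA	no
CYP2C19	*3	NA	no
CYP2C19	*4	NA	no
CYP2C19	*17	NA	increased
CYP3A4	*1	NA	normal
CYP3A4	*2	NA	decreased
CYP3A4	*6	NA	no
CYP3A4	*20	NA	no
CYP3A4	*22	NA	decreased
CYP3A5	*1	NA	normal
CYP3A5	*3	NA	no
CYP3A5	*6	NA	no
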