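# European-population allele frequencies for the transporter variants that are not part
# of a star-allele definition (per-variant Hardy-Weinberg sampling). Frequencies are
# stored as printed in the source population tables; small rounding excess is
# renormalised on load.
rsid	allele	freq
rs1045642	T	0.518
rs1045642	C	0.482
rs2032582	T	0.410
rs2032582	G	0.573
rs2032582	A	0.018
rs1128503	T	0.416
rs1128503	C	0.584
rs2273697	G	0.796
rs2273697	A	0.204
rs2231142	C	0.896
rs2231142	A	0.104
rs12208357	C	0.937
rs12208357	T	0.063
rs34059508	G	0.980
rs34059508	A	0.020
rs72552763	GAT	0.816
rs72552763	delGAT	0.184
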