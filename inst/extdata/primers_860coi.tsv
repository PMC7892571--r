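# Published COI primers for the elongated ascidian barcode fragment and the
# classic Folmer pair, 5'->3'.
name	seq	orientation
dinF	CGTTGRTTTATRTCTACWAATCATAARGA	forward
Nux1R	GCAGTAAAATAWGCTCGRGARTC	reverse
cat1F	ATRTCTACWAATCATAARGATATTRG	forward
ux1R	ATAAGCTCGWGAATCHACATC	reverse
LCO1490	GGTCAACAAATCATAAAGATATTGG	forward
HCO2198	TAAACTTCAGGGTGACCAAAAAATCA	reverse
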