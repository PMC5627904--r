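name	fwd	rev	gene	expected_len
16S	CGCCTGTTTATCAAAAACAT	CCGGTTTGAACTCAGATCA	16S	600
CO1_AmpP3	CAATACCAAACCCCCTTRTTYGTWTGATC	GCTTCTCARATAATAAATATYAT	CO1	900
CO1_LCO1490	GGTCAACAAATCATAAAGATATTGG	TAAACTTCAGGGTGACCAAAAAATCA	CO1	710
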