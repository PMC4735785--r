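chr12	12022747	12037521	ETV6
chr21	36259139	36425395	RUNX1
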