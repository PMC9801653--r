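chr1	1000	1500	50
chr1	1500	1580	1
chr1	1580	2080	50
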