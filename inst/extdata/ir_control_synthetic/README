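Synthetic positive-control fixture for the intron-retention caller.

One gene (ctrlG, chr1:1001-2080, + strand) with a single 80-bp intron
(1501-1580).  Exonic coverage is 50x in all six samples; the intron is
covered flat at 45x in samples ctrl_3 and ctrl_4 only (1x elsewhere), and
the CDS count is 1000 in every sample.  Under the default gates
(T1=30, T2=20, T3=200, T4=0.1; 8-bp bins; scaled ratio, read length 100)
the intron must be called retained in exactly ctrl_3 and ctrl_4.

All files were generated by this package's own writers; nothing here is
derived from real sequencing data.
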