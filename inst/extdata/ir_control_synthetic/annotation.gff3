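##gff-version 3
##source-version rtracklayer 1.62.0
##date 2026-09-26
chr1	scvannotate	gene	1001	2080	.	+	.	ID=ctrlG;gene_id=ctrlG
chr1	scvannotate	exon	1001	1500	.	+	.	gene_id=ctrlG
chr1	scvannotate	exon	1581	2080	.	+	.	gene_id=ctrlG
chr1	scvannotate	CDS	1001	1500	.	+	.	gene_id=ctrlG
chr1	scvannotate	CDS	1581	2080	.	+	.	gene_id=ctrlG
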