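##gff-version 3
toy_seq	introgain	gene	1	220	.	+	.	ID=toyA.gene
toy_seq	introgain	mRNA	1	220	.	+	.	ID=toyA;Parent=toyA.gene
toy_seq	introgain	CDS	1	60	.	+	0	ID=toyA.cds;Parent=toyA
toy_seq	introgain	CDS	161	220	.	+	0	ID=toyA.cds;Parent=toyA
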