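##gff-version 3
##sequence-region chr5 1 230000000
chr5	synthetic	gene	19500000	19700000	.	+	.	ID=geneA;Name=geneA
chr5	synthetic	mRNA	19500000	19700000	.	+	.	ID=geneA.t1;Parent=geneA
chr5	synthetic	gene	19700001	19800000	.	-	.	ID=geneB;Name=geneB
chr5	synthetic	gene	19850000	19860000	.	+	.	ID=geneC;Name=geneC
chr5	synthetic	gene	19912000	20000000	.	+	.	ID=geneD;Name=geneD
chr5	synthetic	gene	20050000	20060000	.	-	.	ID=geneE;Name=geneE
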