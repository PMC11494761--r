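##gff-version 3
##sequence-region chrT 1 1200
chrT	toy	gene	101	520	.	+	.	ID=GA;Name=GA;description=toy gene A
chrT	toy	mRNA	101	520	.	+	.	ID=GA_T1;Parent=GA;canonical=true
chrT	toy	exon	101	220	.	+	.	ID=GA_T1.e1;Parent=GA_T1
chrT	toy	exon	301	520	.	+	.	ID=GA_T1.e2;Parent=GA_T1
chrT	toy	CDS	131	492	.	+	0	ID=GA_T1.c1;Parent=GA_T1
chrT	toy	mRNA	101	520	.	+	.	ID=GA_T2;Parent=GA
chrT	toy	exon	101	520	.	+	.	ID=GA_T2.e1;Parent=GA_T2
chrT	toy	CDS	131	490	.	+	0	ID=GA_T2.c1;Parent=GA_T2
chrT	toy	gene	701	1100	.	-	.	ID=GB;Name=GB;description=toy gene B
chrT	toy	mRNA	701	1100	.	-	.	ID=GB_T1;Parent=GB;canonical=true
chrT	toy	exon	701	860	.	-	.	ID=GB_T1.e1;Parent=GB_T1
chrT	toy	exon	941	1100	.	-	.	ID=GB_T1.e2;Parent=GB_T1
chrT	toy	CDS	731	1071	.	-	0	ID=GB_T1.c1;Parent=GB_T1
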