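chr1	lncpipe	exon	1000	1200	.	+	.	gene_id "RB1_COD1"; transcript_id "RB1_COD1.t"; gene_biotype "protein_coding";
chr1	lncpipe	exon	1500	1700	.	+	.	gene_id "RB1_COD1"; transcript_id "RB1_COD1.t"; gene_biotype "protein_coding";
chr1	lncpipe	exon	2000	2200	.	+	.	gene_id "RB1_COD1"; transcript_id "RB1_COD1.t"; gene_biotype "protein_coding";
chr1	lncpipe	exon	10000	10400	.	+	.	gene_id "RB1_LNC1"; transcript_id "RB1_LNC1.t"; gene_biotype "lncRNA";
chr1	lncpipe	exon	10800	11200	.	+	.	gene_id "RB1_LNC1"; transcript_id "RB1_LNC1.t"; gene_biotype "lncRNA";
chr1	lncpipe	exon	30000	30999	.	-	.	gene_id "RB1_LNC2"; transcript_id "RB1_LNC2.t"; gene_biotype "lncRNA";
chr1	lncpipe	exon	51000	51200	.	+	.	gene_id "RB2_COD1"; transcript_id "RB2_COD1.t"; gene_biotype "protein_coding";
chr1	lncpipe	exon	51500	51700	.	+	.	gene_id "RB2_COD1"; transcript_id "RB2_COD1.t"; gene_biotype "protein_coding";
chr1	lncpipe	exon	52000	52200	.	+	.	gene_id "RB2_COD1"; transcript_id "RB2_COD1.t"; gene_biotype "protein_coding";
chr1	lncpipe	exon	60000	60400	.	+	.	gene_id "RB2_LNC1"; transcript_id "RB2_LNC1.t"; gene_biotype "lncRNA";
chr1	lncpipe	exon	60800	61200	.	+	.	gene_id "RB2_LNC1"; transcript_id "RB2_LNC1.t"; gene_biotype "lncRNA";
chr1	lncpipe	exon	80000	80999	.	-	.	gene_id "RB2_LNC2"; transcript_id "RB2_LNC2.t"; gene_biotype "lncRNA";
chr1	lncpipe	exon	101000	101200	.	+	.	gene_id "RB3_COD1"; transcript_id "RB3_COD1.t"; gene_biotype "protein_coding";
chr1	lncpipe	exon	101500	101700	.	+	.	gene_id "RB3_COD1"; transcript_id "RB3_COD1.t"; gene_biotype "protein_coding";
chr1	lncpipe	exon	102000	102200	.	+	.	gene_id "RB3_COD1"; transcript_id "RB3_COD1.t"; gene_biotype "protein_coding";
chr1	lncpipe	exon	110000	110400	.	+	.	gene_id "RB3_LNC1"; transcript_id "RB3_LNC1.t"; gene_biotype "lncRNA";
chr1	lncpipe	exon	110800	111200	.	+	.	gene_id "RB3_LNC1"; transcript_id "RB3_LNC1.t"; gene_biotype "lncRNA";
chr1	lncpipe	exon	130000	130999	.	-	.	gene_id "RB3_LNC2"; transcript_id "RB3_LNC2.t"; gene_biotype "lncRNA";
chr1	lncpipe	exon	151000	151200	.	-	.	gene_id "RB4_COD1"; transcript_id "RB4_COD1.t"; gene_biotype "protein_coding";
chr1	lncpipe	exon	151500	151700	.	-	.	gene_id "RB4_COD1"; transcript_id "RB4_COD1.t"; gene_biotype "protein_coding";
chr1	lncpipe	exon	152000	152200	.	-	.	gene_id "RB4_COD1"; transcript_id "RB4_COD1.t"; gene_biotype "protein_coding";
chr1	lncpipe	exon	160000	160400	.	+	.	gene_id "RB4_LNC1"; transcript_id "RB4_LNC1.t"; gene_biotype "lncRNA";
chr1	lncpipe	exon	160800	161200	.	+	.	gene_id "RB4_LNC1"; transcript_id "RB4_LNC1.t"; gene_biotype "lncRNA";
chr1	lncpipe	exon	180000	180999	.	-	.	gene_id "RB4_LNC2"; transcript_id "RB4_LNC2.t"; gene_biotype "lncRNA";
chr1	lncpipe	exon	201000	201200	.	-	.	gene_id "RB5_COD1"; transcript_id "RB5_COD1.t"; gene_biotype "protein_coding";
chr1	lncpipe	exon	201500	201700	.	-	.	gene_id "RB5_COD1"; transcript_id "RB5_COD1.t"; gene_biotype "protein_coding";
chr1	lncpipe	exon	202000	202200	.	-	.	gene_id "RB5_COD1"; transcript_id "RB5_COD1.t"; gene_biotype "protein_coding";
chr1	lncpipe	exon	210000	210400	.	+	.	gene_id "RB5_LNC1"; transcript_id "RB5_LNC1.t"; gene_biotype "lncRNA";
chr1	lncpipe	exon	210800	211200	.	+	.	gene_id "RB5_LNC1"; transcript_id "RB5_LNC1.t"; gene_biotype "lncRNA";
chr1	lncpipe	exon	230000	230999	.	-	.	gene_id "RB5_LNC2"; transcript_id "RB5_LNC2.t"; gene_biotype "lncRNA";
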