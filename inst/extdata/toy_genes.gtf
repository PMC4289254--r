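chr1	chromseg	exon	101	368	.	-	.	gene_id "gene0001"; transcript_id "gene0001.t1";
chr1	chromseg	exon	548	697	.	-	.	gene_id "gene0001"; transcript_id "gene0001.t1";
chr1	chromseg	CDS	161	637	.	-	0	gene_id "gene0001"; transcript_id "gene0001.t1";
chr1	chromseg	exon	7741	7927	.	-	.	gene_id "gene0002"; transcript_id "gene0002.t1";
chr1	chromseg	exon	8067	8284	.	-	.	gene_id "gene0002"; transcript_id "gene0002.t1";
chr1	chromseg	exon	8394	8725	.	-	.	gene_id "gene0002"; transcript_id "gene0002.t1";
chr1	chromseg	CDS	7801	8665	.	-	0	gene_id "gene0002"; transcript_id "gene0002.t1";
chr1	chromseg	exon	42132	42520	.	+	.	gene_id "gene0003"; transcript_id "gene0003.t1";
chr1	chromseg	exon	42599	42901	.	+	.	gene_id "gene0003"; transcript_id "gene0003.t1";
chr1	chromseg	CDS	42192	42841	.	+	0	gene_id "gene0003"; transcript_id "gene0003.t1";
chr1	chromseg	exon	3956	4159	.	+	.	gene_id "gene0004"; transcript_id "gene0004.t1";
chr1	chromseg	exon	4321	4538	.	+	.	gene_id "gene0004"; transcript_id "gene0004.t1";
chr1	chromseg	exon	5445	5725	.	+	.	gene_id "gene0004"; transcript_id "gene0004.t1";
chr1	chromseg	exon	6379	6661	.	+	.	gene_id "gene0004"; transcript_id "gene0004.t1";
chr1	chromseg	CDS	4016	6601	.	+	0	gene_id "gene0004"; transcript_id "gene0004.t1";
chr1	chromseg	exon	10253	10619	.	-	.	gene_id "gene0005"; transcript_id "gene0005.t1";
chr1	chromseg	exon	16122	16249	.	-	.	gene_id "gene0005"; transcript_id "gene0005.t1";
chr1	chromseg	exon	16800	17098	.	-	.	gene_id "gene0005"; transcript_id "gene0005.t1";
chr1	chromseg	CDS	10313	17038	.	-	0	gene_id "gene0005"; transcript_id "gene0005.t1";
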