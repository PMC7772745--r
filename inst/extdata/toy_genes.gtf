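#!genome toy
1	toy	gene	110000	120000	.	+	.	gene_id "TG01"; gene_name "A1"; gene_biotype "protein_coding";
1	toy	exon	110000	112000	.	+	.	gene_id "TG01"; exon_number "1";
1	toy	gene	130000	140000	.	-	.	gene_id "TG02"; gene_name "A2"; gene_biotype "protein_coding";
1	toy	gene	150000	160000	.	+	.	gene_id "TG03"; gene_name "A3"; gene_biotype "protein_coding";
1	toy	gene	195000	205000	.	+	.	gene_id "TG04"; gene_name "A4"; gene_biotype "lncRNA";
1	toy	gene	1010000	1020000	.	+	.	gene_id "TG05"; gene_name "B1"; gene_biotype "protein_coding";
1	toy	gene	1030000	1040000	.	-	.	gene_id "TG06"; gene_name "B2"; gene_biotype "protein_coding";
1	toy	gene	1050000	1060000	.	+	.	gene_id "TG07"; gene_name "B3"; gene_biotype "protein_coding";
1	toy	exon	1050000	1052000	.	+	.	gene_id "TG07"; exon_number "1";
1	toy	gene	1095000	1105000	.	-	.	gene_id "TG08"; gene_name "B4"; gene_biotype "protein_coding";
1	toy	gene	2010000	2020000	.	+	.	gene_id "TG09"; gene_name "C1"; gene_biotype "protein_coding";
1	toy	gene	2030000	2040000	.	+	.	gene_id "TG10"; gene_name "C2"; gene_biotype "protein_coding";
1	toy	gene	2050000	2060000	.	-	.	gene_id "TG11"; gene_name "C3"; gene_biotype "protein_coding";
1	toy	gene	2095000	2105000	.	+	.	gene_id "TG12"; gene_name "C4"; gene_biotype "protein_coding";
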