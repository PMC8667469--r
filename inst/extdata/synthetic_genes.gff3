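##gff-version 3
##sequence-region chr05 1 40000000
##sequence-region chr06 1 40000000
chr05	synthetic	gene	36338000	36340000	.	+	.	ID=SynGene0001;description=synthetic kinase-like gene
chr05	synthetic	mRNA	36338000	36340000	.	+	.	ID=SynGene0001.t1;Parent=SynGene0001
chr05	synthetic	gene	36341000	36343500	.	-	.	ID=SynGene0002;description=synthetic wound-induced protein
chr06	synthetic	gene	620000	640000	.	+	.	ID=SynGene0003;description=synthetic calcium-dependent protein kinase
chr06	synthetic	mRNA	620000	640000	.	+	.	ID=SynGene0003.t1;Parent=SynGene0003
chr06	synthetic	gene	698000	699500	.	-	.	ID=SynGene0004;description=synthetic GDP-dissociation inhibitor
chr06	synthetic	gene	880000	882000	.	+	.	ID=SynGene0005;description=synthetic transcription factor
chr06	synthetic	gene	2408000	2410000	.	-	.	ID=SynGene0006;description=synthetic receptor-like kinase
chr06	synthetic	gene	33938000	33939500	.	+	.	ID=SynGene0007;description=synthetic defense response gene
chr06	synthetic	gene	34170000	34170900	.	-	.	ID=SynGene0008;description=synthetic transporter
chr06	synthetic	gene	34316000	34317000	.	+	.	ID=SynGene0009;description=synthetic unknown protein
chr06	synthetic	mRNA	34316000	34317000	.	+	.	ID=SynGene0009.t1;Parent=SynGene0009
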