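# Mutations detected in sequenced loci of the six evolution endpoint
# populations (transcribed from the published study's parallel-evolution
# table).  One row per detected mutation; loci screened but clean are
# absent.  tolC was screened in all populations with no mutations found.
population	gene	coordinate	class	nt_change	protein_change
X1	acrB	481310	SNP	A->C	V773G
X1	hfq	4407590	SNP	T->G	I24M
X1	marC	1625925	SV	IS1 insertion	Disruption
X2	acrA	484383	SNP	T->G	N154T
X2	mdh	3390659	short-indel	+4:GATT	Frameshift
X2	marC	1626084	SV	IS5 insertion	Disruption
X3	acrA	483735	short-indel	+1:A	Frameshift
X3	mdh	3390936	short-indel	+5:AACCT	Frameshift
X3	marC	1626081	SV	IS1 insertion	Disruption
G1	acrA	484669	SNP	G->T	R59S
G1	marC	1625925	SV	IS1 insertion	Disruption
G2	marC	1626100	short-indel	-6:CCACCA	V13-V14 deletion
G3	acrB	480665	SNP	G->A	P988L
G3	mdh	3390726	short-indel	-1:C	Frameshift
G3	hfq	4407505	short-indel	-7:AGGAAAA	RBS deletion
G3	marC	1625925	SV	IS1 insertion	Disruption
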