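# Allele states of X3-lineage loci at genotyped generations.
# Partially synthetic: the 180 (mdtJ-tqsA transposon) and 266
# (mdh/deaD/plsX cluster) first-detection generations and the ordinal
# structure (marC/gatC/hrpA/yfgO first, rpsB before deaD, acrA still
# sweeping at the end) are as reported; all other generations are
# synthetic placeholders consistent with that ordering.
# States: WT wild type, Mut mutant, Mixed mixed population, NT not tested.
locus	generation	state
marC	0	WT
marC	90	Mut
marC	150	Mut
marC	180	Mut
marC	266	Mut
marC	430	Mut
gatC	0	WT
gatC	90	Mut
gatC	150	Mut
gatC	180	Mut
gatC	266	Mut
gatC	430	Mut
hrpA	0	WT
hrpA	90	Mut
hrpA	150	NT
hrpA	180	Mut
hrpA	266	Mut
hrpA	430	Mut
yfgO	0	WT
yfgO	90	Mixed
yfgO	150	Mut
yfgO	180	Mut
yfgO	266	Mut
yfgO	430	Mut
rpsB	0	WT
rpsB	90	WT
rpsB	150	Mut
rpsB	180	Mut
rpsB	266	Mut
rpsB	430	Mut
mdtJ-tqsA	0	WT
mdtJ-tqsA	90	WT
mdtJ-tqsA	150	WT
mdtJ-tqsA	180	Mut
mdtJ-tqsA	266	Mut
mdtJ-tqsA	430	Mut
mdh	0	WT
mdh	90	WT
mdh	150	WT
mdh	180	WT
mdh	266	Mut
mdh	430	Mut
deaD	0	WT
deaD	90	WT
deaD	150	WT
deaD	180	WT
deaD	266	Mut
deaD	430	Mut
plsX	0	WT
plsX	90	WT
plsX	150	WT
plsX	180	WT
plsX	266	Mut
plsX	430	Mut
acrA	0	WT
acrA	90	WT
acrA	150	WT
acrA	180	NT
acrA	266	WT
acrA	430	Mixed
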