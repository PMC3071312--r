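# Per-clone totals of mutations discovered in whole-genome resequencing
# (full per-mutation lists are in the study's supplementary material and
# are not transcribed here; the totals were stated in the text).
# G3 clones carry a mismatch-repair (mutL) loss and are hypermutated.
carrier	n_mutations
G3.2	48
G3.6	64
G3.266.7	8
X3.5	11
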