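# summary counts from a survey of reviewed drug-metabolizing enzymes:
# how many have at least one gut-microbial homolog, how many of those have
# more full-length than split homologs, and drugs metabolized by the latter
metric	value
n_reviewed	154
n_with_homolog	126
n_full_majority	122
n_drugs_full_majority	215
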