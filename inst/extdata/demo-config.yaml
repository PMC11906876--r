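# Demo configuration: a 200-gene synthetic cohort at the generator's
# default study conditions.
n_genes: 200
seed: 20260301
cohort_size: 3115
n_benign: 2000
n_pathogenic: 2000
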