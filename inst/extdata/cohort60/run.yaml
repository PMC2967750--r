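genotypes: dosages.tsv
variant_meta: variants.tsv
genes: genes.bed
phenotypes: phenotypes.tsv
gene_list: candidate_genes.txt
overrides: overrides.tsv
out_dir: out
max_r2: 0.2
window_bp: 5000
alpha: 0.05
low_threshold: 3
high_threshold: 7
folds: 10
null_reps: 100
seed: 1
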