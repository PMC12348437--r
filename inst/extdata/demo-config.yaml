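# Demonstration study: 12 homoeolog members, three of them carrying planted
# causal SNPs on different root traits. Runs end to end in well under five
# minutes on one CPU.
seed: 1
n_members: 12
n_accessions: 114
snps_per_gene_region: 8
causal_spec:
  - member: 3
    trait: TRL
    variance_explained: 0.25
  - member: 7
    trait: RV
    variance_explained: 0.25
  - member: 11
    trait: RTN
    variance_explained: 0.25
n_pcs: 3
neg_log10_threshold: 4
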