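# Small bundled synthetic cohort used by the worked example and the
# end-to-end determinism check.
seed: 1
simulate:
  n_nontoxin_orthologs: 60
  toxin_family_plan: {CTL: 4, SVMP: 4, SVSP: 3, PLA2: 2, BPP: 2}
  cds_codon_range: [80, 150]
  planted_expression_shifts:
    - {transcript_id: PLA2-1, species: B, fold_change: 6}
  te_offsets:
    - {transcript_id: SVMP-1, species: A, offset: -2}
  mirna_plan:
    - {mirna_id: mir-x, count_a: 800, count_b: 150,
       targets: [SVMP-1], site_type: 8mer}
params:
  mirna: {expr_ratio_min: 1, te_quantile: 0.25}
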