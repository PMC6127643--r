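# Bundled synthetic end-to-end configuration: a small paired-design study
# (8 subjects x 5 collection methods for the community table; 4 methods for
# the metabolome, which cannot be assayed from one preservative) with
# report sizes chosen so the full run completes in well under two minutes.
seed: 20180828
bootstrap: 200
n_permutations: 199
icc_level: 0.75
simulate:
  community:
    n_subjects: 8
    n_taxa: 150
    subject_sd: 1.0
    method_sd: 0.3
    depth_mean: 5000
  metabolome:
    n_subjects: 8
    n_features: 150
    censor_quantile: 0.25
    icc_range: [0.2, 0.9]
  scfa:
    n_subjects: 8
    methods: [immediate_freezing, omnigene_gut, fta_card]
    n_features: 10
    censor_quantile: 0.1
    icc_range: [0.5, 0.95]
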