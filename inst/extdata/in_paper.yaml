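# Replay fixture configuration (version 1).
#
# Encodes, as generator parameters, the stage structure of the published
# candidate-gene funnel and mutant screen so that the pipeline's planted-
# truth replay reproduces the printed counts:
#   - 2993 clade-unique genes across a 19-genome pan-genome (2 targets),
#   - 7 of them unexpressed (zero mapped counts),
#   - 10 biosynthetic core genes among the unique-and-expressed set
#     (the focal 5-gene PKS-NRPS cluster plus one additional cluster),
#   - 7 complete-loss UV mutants split 5 (T1-PKS) / 2 (NRPS), 2 reduced,
#   - mean background mutation load 4 per strain.
fixture_version: 1
n_genomes: 19
n_core: 1200
n_shell: 600
n_unique: 2993
n_target_partial: 25
n_near_unique: 25
n_zero_expression: 7
nb_mean: 200
nb_size: 5
n_background_genes: 60
n_extra_clusters: 1
mutation_lambda: 4
n_lost: 7
n_reduced: 2
n_wt: 1
causal_split:
  t1pks: 5
  nrps: 2
n_artifact_variants: 3
n_drops: 30
n_dilutions: 6
n_replicates: 3
start_cfu_per_ml: 1.0e+8
drop_volume_ul: 20
spectrum_onset: -4
spectrum_log_slope: 0.7
spectrum_k_onset: 1.0e-07
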