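Published leave-one-allele-out benchmark statistics for class II MHC
binding prediction, transcribed from the printed comparison tables:

  hla_dr_loao.tsv         pan-allotype cross-validation for 14 HLA-DR
                          allotypes (AUC, RMS error in kcal/mol, Pearson r)
                          alongside NetMHCIIpan and TEPITOPE AUCs on the
                          same data sets
  hla_dp_loao.tsv         pan-allotype cross-validation for 5 HLA-DP
                          allotypes
  hla_dr_nearest_rta.tsv  single-allotype nearest-neighbour baseline for
                          the same 14 HLA-DR allotypes
  hla_dp_nearest_rta.tsv  single-allotype baseline for the 5 HLA-DP
                          allotypes

These tables are inputs to the benchmark-statistics reproduction (method
agreement correlation and exact Wilcoxon signed-rank comparisons); the
underlying per-peptide training data are external and not shipped.
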