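# Default annotation run configuration: three adducts (ammonium, sodium,
# potassium), two neutral losses (ammonia, water), dimers and trimers,
# combinations to depth 3, absolute tolerance 10 mmu; intensity thresholds
# 500 cps absolute and 1% relative, deisotoping ratio window 1-100%,
# monoisotopic validation on.
filter:
  abs_intensity_min: 500
  rel_intensity_min: 1
  isotope_ratio_range: [1, 100]
  isotope_tolerance: 0.010
  monoisotopic_validation: true
annotation:
  base_deltas: [NH3_adduct, Na_adduct, K_adduct, H2O_loss, NH3_loss]
  multimers: [1, 2, 3]
  max_depth: 3
  tolerance_mmu: 10
  polarity: positive
io:
  graph_format: graphml
seed: 1
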