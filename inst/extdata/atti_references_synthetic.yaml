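# Bundled attI reference metadata. These references are SYNTHETIC
# stand-ins: constructed sequences satisfying the published structural
# constraints of the canonical sites (attI1: 65 bp, direct repeats
# DR1/DR2, L box CCCTAAA, R box realizing GTTRRRY, crossover G closing a
# -56 upstream extent; attI2: 311 bp region ending AATAAAATG + TTRRRY),
# screened so no unintended core or consensus motif occurs. Replace with
# the GenBank-derived sites (attI1: NC_028464; attI2: DQ176450) for work
# on real records.
attI1:
  id: attI1_synthetic
  class_label: 1
  crossover_g_index: 56
  length: 65
  source: "synthetic stand-in for the canonical 65 bp attI1 site (cited from NC_028464)"
  boxes:
    DR1: [4, 10]
    DR2: [18, 24]
    L_box: [32, 38]
    R_box: [56, 62]
attI2:
  id: attI2_synthetic
  class_label: 2
  crossover_g_index: 305
  length: 311
  source: "synthetic stand-in for the ~311 bp attI2 region (cited from DQ176450)"
  boxes: {}
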