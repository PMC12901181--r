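# Consensus motifs over the IUPAC alphabet (R = purine, Y = pyrimidine).
# dattI1/dattI2 are the minimal truncated-attI consensus sequences;
# core_site is the attC R' (CS), inverse_core the attC R'' (ICS),
# l_box the attI1 L box.
dattI1: AAACAAAGTTRRRY
dattI2: AATAAAATGTTRRRY
core_site: GTTRRRY
inverse_core: RYYYAAC
l_box: CCCTAAA
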