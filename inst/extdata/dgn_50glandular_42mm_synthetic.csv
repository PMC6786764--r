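# synthetic stand-in for monoenergetic normalized glandular dose coefficients
# (mGy glandular dose per R entrance exposure); magnitudes are plausible for a
# 4.2 cm compressed breast at 50% glandularity but are NOT reference values --
# supply a literature table for quantitative dosimetry
# breast_thickness_cm: 4.2
# glandularity: 0.5
energy_keV,dgn_mgy_per_r
15,0.12
20,0.38
25,0.60
30,0.76
35,0.87
40,0.95
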