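# material: breast
# 50%/50% glandular/adipose breast tissue, density 0.98 g/cm^3
# representative magnitudes from standard photon cross-section compilations
energy_keV,mu_per_cm
15,1.274
18,0.813
20,0.666
25,0.459
30,0.350
35,0.295
40,0.262
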