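# material: water
# liquid water, density 1.00 g/cm^3
# representative magnitudes from standard photon cross-section compilations
energy_keV,mu_per_cm
15,1.673
18,1.057
20,0.810
25,0.537
30,0.376
35,0.314
40,0.268
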