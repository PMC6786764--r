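# material: pmma
# polymethyl methacrylate, density 1.19 g/cm^3
# representative magnitudes from standard photon cross-section compilations
energy_keV,mu_per_cm
15,1.310
20,0.680
25,0.488
30,0.361
35,0.317
40,0.279
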