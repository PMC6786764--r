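# mass energy-absorption coefficient of dry air, cm^2/g
# representative magnitudes from standard photon cross-section compilations
energy_keV,muen_cm2_g
15,1.334
18,0.751
20,0.5389
25,0.270
30,0.1537
35,0.0996
40,0.06833
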