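# material: calcium
# linear attenuation of elemental calcium (density 1.55 g/cm^3)
# representative magnitudes from standard photon cross-section compilations;
# 25 and 35 keV entries are the decomposition-basis anchor values
energy_keV,mu_per_cm
15,45.8
18,27.1
20,20.0
22,15.2
25,10.650
28,7.66
30,6.28
32,5.22
35,4.097
40,2.92
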