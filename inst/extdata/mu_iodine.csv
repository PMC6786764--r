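# material: iodine
# linear attenuation of elemental iodine (density 4.93 g/cm^3)
# representative magnitudes from standard photon cross-section compilations;
# 25 and 35 keV entries are the decomposition-basis anchor values
# K edge at 33.17 keV carried as two grid points 4 eV apart
energy_keV,mu_per_cm
15,296.0
18,176.0
20,130.0
22,98.5
25,68.796
28,49.6
30,40.6
32,33.7
33.168,30.3
33.172,181.0
34,167.4
35,154.109
37,131.0
40,104.5
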