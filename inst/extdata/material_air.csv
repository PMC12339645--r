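# Dry air near sea level, percent by weight.
name,air
mass_density_g_cm3,0.0012
element,mass_fraction_percent
N,75.5
O,23.2
Ar,1.3
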