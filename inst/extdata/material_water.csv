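# Stoichiometric H2O, percent by weight.
name,water
mass_density_g_cm3,1.00
element,mass_fraction_percent
H,11.19
O,88.81
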