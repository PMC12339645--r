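# ICRP Publication 110 reference adult brain (whole brain,
# white and gray matter not distinguished). Percent by weight.
name,ICRP110 brain
mass_density_g_cm3,1.05
element,mass_fraction_percent
H,10.70
C,14.30
N,2.30
O,71.30
Na,0.20
P,0.40
S,0.20
Cl,0.30
K,0.30
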