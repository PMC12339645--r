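# Gammex Brain SR-2 brain-tissue-equivalent density plug,
# elemental analysis (CHNS/O + XRF). Percent by weight.
# Elements reported only as "< 0.01" (Al, P, S, K, Fe) are omitted.
name,BDP
mass_density_g_cm3,1.05
element,mass_fraction_percent
H,10.36
B,1.08
C,73.26
N,1.99
O,12.52
Na,0.06
Mg,0.05
Si,0.01
Cl,0.64
Ca,0.01
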