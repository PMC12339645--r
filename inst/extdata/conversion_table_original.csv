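# variant=original
# Clinical CT-RED/MD calibration table (plug-based).
# Only knots whose printed values are unambiguous are included,
# plus the brain-plug (BDP) knot. The BDP knot's HU is not reliably
# legible in the source document; the value below is a best-effort
# transcription and is marked by material=BDP. Treat it as uncertain.
hu,red,md,material
-1000,0.001,0.001,air
-703,0.28,0.29,
-528,0.445,0.46,
-102,0.926,0.943,
-42,0.959,0.982,
0,1,1,water
26,1.052,1.054,BDP
427,1.277,1.332,
777,1.477,1.56,
1228,1.695,1.823,
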