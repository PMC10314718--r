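tissue,mu_cm1,energy_keV
background,0.000,30
fat,0.288,30
glandular,0.380,30
skin,0.400,30
artery,0.460,30
vein,0.455,30
muscle,0.440,30
ligament,0.420,30
nipple,0.405,30
tdlu,0.392,30
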