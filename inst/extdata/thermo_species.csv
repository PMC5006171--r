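species,dGf_kJmol,dHf_kJmol,charge,formula
H,0,0,1,H1
H2,17.57,-4.18,0,H2
H2O,-237.18,-285.83,0,H2O1
CH4,-34.39,-89.04,0,C1H4
HCO3,-586.8,-692.0,-1,C1H1O3
SO4,-744.0,-909.27,-2,S1O4
HS,12.05,-17.6,-1,H1S1
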