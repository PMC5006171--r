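,HCO3,CH4,SO4,HS
AOM_ilr.1,1,-1,-1,1
AOM_ilr.2,1,0,0,-1
AOM_ilr.3,0,1,-1,0
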