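,SO4,H2,H,HS
SO4_ilr.1,-1,-1,-1,1
SO4_ilr.2,-1,1,-1,0
SO4_ilr.3,1,0,-1,0
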