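column,type,units,description
sample_id,text,,unique well/sample identifier
aquifer_group,enum,,one of ALLUVIUM SHALLOW_COAL_MEASURES GAS_RESERVOIR KUMBARILLA
screen_depth,numeric,m,screen depth of the sampled interval
temperature,numeric,degC,field water temperature (required)
pH,numeric,,field pH (required)
DO,numeric,mg/L,dissolved oxygen
Na,censored,mg/L,sodium; cell may carry a "<DL" prefix
K,censored,mg/L,potassium
Ca,censored,mg/L,calcium
Mg,censored,mg/L,magnesium
HCO3,censored,mg/L,bicarbonate alkalinity (as HCO3)
Cl,censored,mg/L,chloride
Br,censored,mg/L,bromide
SO4,censored,mg/L,sulfate
NO3,censored,mg/L,nitrate
S2,censored,mg/L,sulfide (S2-; equivalent weight 64.13 g/mol)
HS,censored,mg/L,unionised hydrogen sulfide
Fe,censored,mg/L,total dissolved iron
Mn,censored,mg/L,total dissolved manganese
CH4,censored,ug/L,dissolved methane (note: ug/L not mg/L)
<species>_dl,numeric,same as species,per-cell detection limit (optional; defaults apply)
<species>_cens,logical,,TRUE when the cell is below the detection limit (optional)
DOC,numeric,mg/L,dissolved organic carbon
tritium,numeric,TU,tritium activity
d13C_CH4,numeric,per mil,delta 13C of methane (VPDB)
d2H_CH4,numeric,per mil,delta 2H of methane (VSMOW)
d13C_DIC,numeric,per mil,delta 13C of dissolved inorganic carbon (VPDB)
d2H_H2O,numeric,per mil,delta 2H of water (VSMOW)
d18O_H2O,numeric,per mil,delta 18O of water (VSMOW)
d37Cl,numeric,per mil,delta 37Cl (SMOC)
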