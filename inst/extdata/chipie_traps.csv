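experiment,treatment,poc_percent,poc_stock_mmol,poc_stock_mg,al_percent,al_mass_mg
CHIPIE 1,NA,1.6,1.1,13.8,5.3,46.0
CHIPIE 1,A,1.6,1.2,13.9,5.4,46.8
CHIPIE 2,NA,1.5,2.7,32.4,4.9,108.4
CHIPIE 2,A,1.5,2.6,31.3,5.1,109.2
CHIPIE 3,NA,1.3,2.0,24.3,4.4,81.1
CHIPIE 3,A,1.6,2.5,29.4,4.9,91.8
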