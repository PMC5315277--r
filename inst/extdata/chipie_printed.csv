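experiment,treatment,poc_flux_total,poc_flux_daily,dust_exported_percent,litho_flux_total
CHIPIE 1,NA,38.2,6.4,31.0,3100
CHIPIE 1,A,38.7,6.4,31.6,3160
CHIPIE 2,NA,90.1,15.0,73.1,7310
CHIPIE 2,A,87.1,14.5,73.7,7370
CHIPIE 3,NA,67.5,11.3,54.6,5460
CHIPIE 3,A,81.7,13.6,61.9,6190
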