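study,ration_mg_per_larva_d,f,profile
growth_reproduction_experiment,0.6,1.00,variable
growth_reproduction_experiment,0.3,0.58,variable
growth_reproduction_experiment,0.15,0.25,variable
growth_reproduction_experiment,0.1,0.12,variable
literature_growth,0.4,1.23,constant
literature_growth,0.3,1.00,constant
literature_growth,0.2,0.83,constant
literature_growth,0.1,0.46,constant
literature_sex_comparison,1.4,1.93,constant
literature_temperature_adlib,NA,1.50,constant
literature_temperature_limited,0.2,0.84,constant
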