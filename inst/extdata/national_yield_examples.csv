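country,crop,water_regime,converted_yield_t_ha,new_yield_t_ha
China,rice,irrigated,15.2,11.8
Indonesia,rice,irrigated and rainfed,16.9,13.4
Nigeria,maize,rainfed,11.6,8.5
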