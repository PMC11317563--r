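community,replacement_category,price_cad_per_kg
Aklavik,poultry,13.50
Aklavik,fish_mix,31.00
Aklavik,beef_pork_mix,25.00
Inuvik,poultry,12.00
Inuvik,fish_mix,29.50
Inuvik,beef_pork_mix,23.50
Paulatuk,poultry,15.00
Paulatuk,fish_mix,33.50
Paulatuk,beef_pork_mix,27.00
Sachs Harbour,poultry,16.00
Sachs Harbour,fish_mix,34.50
Sachs Harbour,beef_pork_mix,28.00
Tuktoyaktuk,poultry,13.00
Tuktoyaktuk,fish_mix,30.50
Tuktoyaktuk,beef_pork_mix,24.50
Ulukhaktok,poultry,15.50
Ulukhaktok,fish_mix,34.00
Ulukhaktok,beef_pork_mix,27.50
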