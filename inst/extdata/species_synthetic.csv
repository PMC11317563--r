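species_code,species_type,taxon_class,edible_weight_kg_per_animal,replacement_category
CAGO,geese,bird,2.4,poultry
SNGO,geese,bird,1.6,poultry
GWFG,geese,bird,2.0,poultry
MALL,ducks,bird,0.9,poultry
KIEI,ducks,bird,1.0,poultry
PTAR,ptarmigan,bird,0.4,poultry
BDWF,whitefish,fish,2.5,fish_mix
LKWF,whitefish,fish,1.8,fish_mix
INCO,inconnu,fish,4.5,fish_mix
ARCH,char_trout,fish,2.4,fish_mix
LKTR,char_trout,fish,2.7,fish_mix
CARI,caribou,mammal,46.0,beef_pork_mix
MUSK,muskox,mammal,101.0,beef_pork_mix
RISE,seals,mammal,22.0,beef_pork_mix
MOOS,moose,mammal,150.0,beef_pork_mix
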