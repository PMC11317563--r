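# Synthetic example configuration: values are order-of-magnitude realistic
# for the western Canadian Arctic but are NOT measured reference values.
# Units: production_ef in kg CO2e per kg edible; transport_ef in
# kg CO2e per kg per km; distances in km; prices/costs in CAD.

cpi_factor: 0.989

production_ef:
  poultry: 2.6
  fish_mix: 3.3
  beef_pork_mix: 12.5

transport_ef:
  road:  {low: 0.00008, high: 0.00012}
  rail:  {low: 0.00002, high: 0.00005}
  barge: {low: 0.00002, high: 0.00006}
  air:   {low: 0.00080, high: 0.00150}

routes:
  barge:
    Aklavik:       [{mode: road, km: 1150}, {mode: barge, km: 1900}]
    Inuvik:        [{mode: road, km: 1150}, {mode: barge, km: 1800}]
    Paulatuk:      [{mode: road, km: 1150}, {mode: barge, km: 2300}]
    Sachs Harbour: [{mode: road, km: 1150}, {mode: barge, km: 2500}]
    Tuktoyaktuk:   [{mode: road, km: 1150}, {mode: barge, km: 1950}]
    Ulukhaktok:    [{mode: road, km: 1150}, {mode: barge, km: 2700}]
  foodmail:
    Aklavik:       [{mode: road, km: 3550}, {mode: air, km: 110}]
    Inuvik:        [{mode: road, km: 3550}]
    Paulatuk:      [{mode: road, km: 3550}, {mode: air, km: 400}]
    Sachs Harbour: [{mode: road, km: 3550}, {mode: air, km: 520}]
    Tuktoyaktuk:   [{mode: road, km: 3690}]
    Ulukhaktok:    [{mode: road, km: 3550}, {mode: air, km: 900}]

fuel:
  gasoline_density_kg_per_l: 0.749
  combustion_ef_kg_per_l: 2.319
  fuel_price_cad_per_l: 1.76
  route: [{mode: rail, km: 1500}, {mode: barge, km: 1900}]
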