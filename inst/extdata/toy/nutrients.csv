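item_code,energy_kj,energy_kcal,sat_fat_g,total_sugars_g,free_sugars_g,sodium_mg,salt_g,fibre_g,fibre_basis,protein_g,fvn_pct
F001,800,191.20458891013382,0,50,50,0,0,0,AOAC,0,0
F002,800,191.20458891013382,0,50,50,0,0,0,AOAC,0,0
F003,800,191.20458891013382,0,0,0,0,0,0,AOAC,0,0
F004,800,191.20458891013382,0,0,0,0,0,0,AOAC,0,0
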