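# UK Nutrient Profiling Model, 2004/05 (Ofcom) variant.
# Band values transcribed from the FSA/DH Nutrient Profiling Technical
# Guidance threshold tables (per 100 g; a band is entered when the value
# STRICTLY exceeds the cutpoint).
name: NPM2004
status: final
sugar_field: total_sugars_g
sodium_field: sodium_mg
a_bands:
  energy_kj: [335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350]
  sat_fat_g: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
  sugars_g: [4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45]
  sodium: [90, 180, 270, 360, 450, 540, 630, 720, 810, 900]
c_bands:
  fvn_pct:
    cutpoints: [40, 60, 80]
    points: [1, 2, 5]
  fibre:
    NSP: [0.7, 1.4, 2.1, 2.8, 3.5]
    AOAC: [0.9, 1.9, 2.8, 3.7, 4.7]
  protein_g: [1.6, 3.2, 4.8, 6.4, 8.0]
protein_cap:
  a_threshold: 11
  exemption_fvn_points: 5
cutoffs:
  food: 4
  drink: 1
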