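# UK Nutrient Profiling Model, 2018 consultation variant. PROVISIONAL.
#
# Encodes the publicly stated deltas from the 2004/05 model: free sugars
# replace total sugars, salt replaces sodium, the fibre (AOAC) component is
# rescaled for a 30 g (was 24 g) reference intake, and the energy component
# for an 8400 kJ (was 8950 kJ) reference. Energy cutpoints are the 2004/05
# cutpoints scaled by 8400/8950 (rounded to a 315 kJ step); fibre cutpoints
# are scaled by 30/24. Sugar cutpoints are carried over unchanged and applied
# to free sugars, and salt cutpoints are the sodium cutpoints expressed as
# salt (x 2.5 / 1000). Replace this file with transcribed consultation tables
# before using the 2018 variant for anything other than sensitivity analysis.
name: NPM2018
status: provisional
sugar_field: free_sugars_g
sodium_field: salt_g
a_bands:
  energy_kj: [315, 630, 945, 1260, 1575, 1890, 2205, 2520, 2835, 3150]
  sat_fat_g: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
  sugars_g: [4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45]
  sodium: [0.225, 0.45, 0.675, 0.9, 1.125, 1.35, 1.575, 1.8, 2.025, 2.25]
c_bands:
  fvn_pct:
    cutpoints: [40, 60, 80]
    points: [1, 2, 5]
  fibre:
    AOAC: [1.13, 2.38, 3.5, 4.63, 5.88]
  protein_g: [1.6, 3.2, 4.8, 6.4, 8.0]
protein_cap:
  a_threshold: 11
  exemption_fvn_points: 5
cutoffs:
  food: 4
  drink: 1
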