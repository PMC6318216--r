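# Example column map: canonical field -> column name in the input file.
# Masses are kilograms on disk; volume is cubic metres.
column_map:
  species: species
  tree_id: tree_id
  dbh_cm: dbh_cm
  height_m: height_m
  volume_m3: volume_m3
  w_stem: stem_kg
  w_branches: branches_kg
  w_foliage: foliage_kg
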