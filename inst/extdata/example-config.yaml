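paths:
  peak_table: synthetic_peak_table.csv
  library: synthetic_library.csv
  training: synthetic_training.csv
  output: organized_matrix.csv
time_width_c: 2.0
anchors:
- compound_001
- compound_006
alpha: 0.05
df_convention: paper
min_doc: 0.0
rt_tolerance: 1.5
seed: 1.0
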