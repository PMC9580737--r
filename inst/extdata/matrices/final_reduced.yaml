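# Final reduced system: only the four categories with predictive value
# (Gram-positive diplococci, combined Gram-negative rods, immune cells,
# mature epithelial cells).
matrix_id: final_reduced
cutoff: youden
rules:
- category: gp_diplococci
  op: range
  lo: 0.0
  hi: 1.0
  points: 1
- category: gn_rods_combined
  op: lt
  threshold: 15.0
  points: 2
- category: immune_cells
  op: gt
  threshold: 1.0
  points: 3
- category: mature_ec
  op: eq0
  points: 1
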