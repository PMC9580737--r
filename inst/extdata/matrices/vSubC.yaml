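# Expanded score-based system: long and short Gram-negative rods combined
# into one category, Gram-positive cocci/rod directions reversed.
matrix_id: vSubC
cutoff: youden
rules:
- category: gp_cocci
  op: gt
  threshold: 7.0
  points: 1
- category: gp_rods
  op: gt
  threshold: 4.0
  points: 1
- category: gp_diplococci
  op: range
  lo: 0.0
  hi: 1.0
  points: 1
- category: gn_cocci
  op: eq0
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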