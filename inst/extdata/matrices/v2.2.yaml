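# Follows the published cells verbatim, including the zero-weighted
# Gram-positive rod rule; the possible total of 10 only sums with it.
matrix_id: v2.2
cutoff:
  value: 6.0
  orientation: ge
rules:
- category: gp_cocci
  op: lt
  threshold: 7.0
  points: 1
- category: gp_rods
  op: lt
  threshold: 4.0
  points: 0
- category: gp_diplococci
  op: lt
  threshold: 1.0
  points: 1
- category: gn_cocci
  op: lt
  threshold: 1.0
  points: 2
- category: gn_rods_short
  op: lt
  threshold: 15.0
  points: 1
- category: gn_rods_long
  op: lt
  threshold: 2.0
  points: 1
- category: immune_cells
  op: gt
  threshold: 0.0
  points: 3
- category: mature_ec
  op: lt
  threshold: 1.0
  points: 1
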