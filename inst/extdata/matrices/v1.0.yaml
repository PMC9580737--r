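# First-pass system: points assigned from p-value bands on the subsample A
# group comparisons. Gram-negative cocci were not yet scored.
matrix_id: v1.0
cutoff:
  value: 6.0
  orientation: ge
rules:
- category: gp_cocci
  op: lt
  threshold: 5.0
  points: 1
- category: gp_rods
  op: lt
  threshold: 4.0
  points: 1
- category: gp_diplococci
  op: lt
  threshold: 1.0
  points: 1
- category: gn_rods_short
  op: lt
  threshold: 10.0
  points: 2
- category: gn_rods_long
  op: lt
  threshold: 1.0
  points: 2
- category: immune_cells
  op: gt
  threshold: 1.0
  points: 3
- category: mature_ec
  op: lt
  threshold: 1.0
  points: 1
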