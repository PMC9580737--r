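# Default synthetic-cohort generator configuration. Per-category count
# targets are the published subsample A group means/SDs; the cytokine OD
# model is log-normal with a log-scale shift for inflamed samples sized so
# that 3-of-4 binary-median labeling recovers true status in ~95% of
# samples at equal group sizes.
n_inflamed: 100
n_normal: 100
images_per_sample: [2, 5]
quality_fail_rate: 0.05
sample_effect_sd: 0.2
count_family: nbinom
counts:
  gp_cocci:        {mean_inflamed: 5.4, sd_inflamed: 9.1, mean_normal: 8.8, sd_normal: 9.3}
  gp_rods:         {mean_inflamed: 3.6, sd_inflamed: 7.0, mean_normal: 7.6, sd_normal: 11.0}
  gp_diplococci:   {mean_inflamed: 0.4, sd_inflamed: 1.1, mean_normal: 1.5, sd_normal: 2.4}
  gp_pleomorphic:  {mean_inflamed: 0.6, sd_inflamed: 2.7, mean_normal: 1.0, sd_normal: 2.4}
  gn_cocci:        {mean_inflamed: 17.3, sd_inflamed: 10.8, mean_normal: 15.0, sd_normal: 9.1}
  gn_rods_short:   {mean_inflamed: 8.3, sd_inflamed: 8.1, mean_normal: 16.7, sd_normal: 12.3}
  gn_rods_long:    {mean_inflamed: 0.5, sd_inflamed: 1.4, mean_normal: 1.9, sd_normal: 2.9}
  immune_cells:    {mean_inflamed: 2.0, sd_inflamed: 2.8, mean_normal: 0.1, sd_normal: 0.3}
  mature_ec:       {mean_inflamed: 0.4, sd_inflamed: 1.2, mean_normal: 0.8, sd_normal: 1.2}
  intermediate_ec: {mean_inflamed: 0.4, sd_inflamed: 0.8, mean_normal: 0.3, sd_normal: 0.6}
  parabasal_ec:    {mean_inflamed: 0.2, sd_inflamed: 0.5, mean_normal: 0.1, sd_normal: 0.6}
# Fraction of fields where mucus is present (39/99 inflamed, 12/72 normal
# in the published summary); grade uniform 1-3 among mucus-positive fields.
mucus_prevalence: {inflamed: 0.394, normal: 0.167}
# Fraction of fields flagged scant bacteria (50/98 inflamed, 25/72 normal).
scant_prob: {inflamed: 0.51, normal: 0.347}
cytokines:
  sdlog: 0.5
  inflamed_shift_log: 1.2
  baseline_meanlog:
    TNFA: 0.0
    IL8: 0.0
    IL1B: 0.0
    CXCL10: 0.0
    IL6: -3.0
    IL17A: -3.0
target_label_agreement: 0.95
ct:
  levels: [CT1, CT2, CT3, CT4, CT5]
  probs: [0.30, 0.25, 0.20, 0.15, 0.10]
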