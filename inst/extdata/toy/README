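Synthetic toy example tables in the pipeline's CSV formats, produced by
generate_cohort(generator_config(n_inflamed = 4, n_normal = 4), seed = 11).
They exist so the command-line examples have ready-made inputs; they are
not data from any study.
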