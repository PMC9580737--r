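sample_id,community_type
S0001,CT1
S0002,CT1
S0003,CT2
S0004,CT1
S0005,CT1
S0006,CT5
S0007,CT1
S0008,CT1
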