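AT_MLS_A
AT_PKT_A
AT_TTL_A
AT_HIT_A
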