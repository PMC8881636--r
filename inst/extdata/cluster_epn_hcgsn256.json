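{"name":"occipito_parietal","sensor_ids":[106,107,108,113,114,115,116,117,121,122,123,124,125,126,133,134,135,136,137,138,139,145,146,147,148,149,150,151,156,157,158,159,160,165,166,167,168,169,174,175,176]}
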