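{"name":"centro_parietal","sensor_ids":[6,7,8,9,15,16,17,23,24,30,42,43,44,45,51,52,53,59,60,79,80,81,89,130,131,132,143,144,155,183,184,185,186,196,197,198,206,207,215,257]}
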