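compartment	n_events
A	13
D	15
scaffold	14
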