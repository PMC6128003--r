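n_nterm_malectin	n_members
9	13
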