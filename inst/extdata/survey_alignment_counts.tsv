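ca_class	n_before	n_removed
alpha	242	5
beta	557	29
gamma	506	217
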