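strain_label	cfu
wt	50000000
mut	50000000
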