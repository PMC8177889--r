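sample_id	group	target_ct	reference_ct
q01	control	26.1	18.2
q02	control	25.8	18.0
q03	control	26.3	18.4
q04	control	26.0	18.1
q05	treated	23.1	18.2
q06	treated	22.8	18.0
q07	treated	23.3	18.3
q08	treated	22.9	17.9
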