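animal_id	compartment	strain_label	colony_count	dilution_exponent	plated_volume_ml	homogenate_volume_ml	sample_mass_g
m01	colon	wt	182	4	0.1	1	0.1
m01	colon	mut	151	3	0.1	1	0.1
m02	colon	wt	95	4	0.1	1	0.1
m02	colon	mut	88	3	0.1	1	0.1
m03	colon	wt	240	4	0.1	1	0.1
m03	colon	mut	132	3	0.1	1	0.1
m04	colon	wt	310	4	0.1	1	0.1
m04	colon	mut	205	3	0.1	1	0.1
m05	colon	wt	128	4	0.1	1	0.1
m05	colon	mut	61	3	0.1	1	0.1
m06	colon	wt	205	4	0.1	1	0.1
m06	colon	mut	0	0	0.1	1	0.1
m07	colon	wt	176	4	0.1	1	0.1
m07	colon	mut	89	3	0.1	1	0.1
m08	colon	wt	290	4	0.1	1	0.1
m08	colon	mut	152	3	0.1	1	0.1
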