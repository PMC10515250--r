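analyte	unit	wt	shn2
total_cutin	ug_per_cm2	1674	302
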