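stage	n_dimorphic
fetal	394
adult	1488
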