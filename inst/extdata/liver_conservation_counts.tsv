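class	fetal_dimorphic	also_adult
autosome	369	264
X	21	14
Y	4	4
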