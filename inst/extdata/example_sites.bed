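example_locus	20	35	activator	2	.
example_locus	60	95	promoter	2	.
example_locus	120	138	repressor	-2	.
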