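symbol	beta	var_explained
GENE002	0.991004546055757	0.356434603960698
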