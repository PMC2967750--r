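GENE001
GENE002
GENE003
GENE004
GENE005
GENE006
GENE007
GENE008
GENE009
GENE010
GENE011
GENE012
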