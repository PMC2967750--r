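chrS1	20000	80000	GENE001
chrS1	120000	180000	GENE002
chrS1	220000	280000	GENE003
chrS1	320000	380000	GENE004
chrS1	420000	480000	GENE005
chrS1	520000	580000	GENE006
chrS1	620000	680000	GENE007
chrS1	720000	780000	GENE008
chrS1	820000	880000	GENE009
chrS1	920000	980000	GENE010
chrS2	20000	80000	GENE011
chrS2	120000	180000	GENE012
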