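variant_id	chrom	pos	ref	alt
rs001001	chrS1	21001	A	G
rs001002	chrS1	50001	A	G
rs001003	chrS1	79001	A	G
rs002001	chrS1	121001	A	G
rs002002	chrS1	130668	A	G
rs002003	chrS1	140334	A	G
rs002004	chrS1	150001	A	G
rs002005	chrS1	159668	A	G
rs002006	chrS1	169334	A	G
rs002007	chrS1	179001	A	G
rs003001	chrS1	221001	A	G
rs003002	chrS1	250001	A	G
rs003003	chrS1	279001	A	G
rs004001	chrS1	321001	A	G
rs004002	chrS1	350001	A	G
rs004003	chrS1	379001	A	G
rs005001	chrS1	421001	A	G
rs005002	chrS1	440334	A	G
rs005003	chrS1	459668	A	G
rs005004	chrS1	479001	A	G
rs006001	chrS1	521001	A	G
rs006002	chrS1	532601	A	G
rs006003	chrS1	544201	A	G
rs006004	chrS1	555801	A	G
rs006005	chrS1	567401	A	G
rs006006	chrS1	579001	A	G
rs007001	chrS1	621001	A	G
rs007002	chrS1	640334	A	G
rs007003	chrS1	659668	A	G
rs007004	chrS1	679001	A	G
rs008001	chrS1	721001	A	G
rs008002	chrS1	740334	A	G
rs008003	chrS1	759668	A	G
rs008004	chrS1	779001	A	G
rs009001	chrS1	821001	A	G
rs009002	chrS1	850001	A	G
rs009003	chrS1	879001	A	G
rs010001	chrS1	921001	A	G
rs010002	chrS1	932601	A	G
rs010003	chrS1	944201	A	G
rs010004	chrS1	955801	A	G
rs010005	chrS1	967401	A	G
rs010006	chrS1	979001	A	G
rs011001	chrS2	21001	A	G
rs011002	chrS2	50001	A	G
rs011003	chrS2	79001	A	G
rs012001	chrS2	121001	A	G
rs012002	chrS2	130668	A	G
rs012003	chrS2	140334	A	G
rs012004	chrS2	150001	A	G
rs012005	chrS2	159668	A	G
rs012006	chrS2	169334	A	G
rs012007	chrS2	179001	A	G
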