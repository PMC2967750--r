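sample_id	rs001001	rs001002	rs001003	rs002001	rs002002	rs002003	rs002004	rs002005	rs002006	rs002007	rs003001	rs003002	rs003003	rs004001	rs004002	rs004003	rs005001	rs005002	rs005003	rs005004	rs006001	rs006002	rs006003	rs006004	rs006005	rs006006	rs007001	rs007002	rs007003	rs007004	rs008001	rs008002	rs008003	rs008004	rs009001	rs009002	rs009003	rs010001	rs010002	rs010003	rs010004	rs010005	rs010006	rs011001	rs011002	rs011003	rs012001	rs012002	rs012003	rs012004	rs012005	rs012006	rs012007
S0001	1	0	1	0	0	0	0	0	0	2	1	2	2	0	0	0	2	1	1	1	0	1	1	0	1	1	0	0	1	0	1	1	0	0	1	1	0	0	0	1	0	0	1	0	0	1	0	1	0	2	1	0	0
S0002	2	1	0	0	1	1	0	0	0	1	0	0	0	0	0	0	1	0	1	0	0	1	1	1	1	0	0	0	1	1	0	0	0	0	1	0	1	0	0	0	1	1	0	0	0	2	1	2	0	0	0	1	0
S0003	0	0	1	0	1	2	1	1	0	1	0	0	0	0	0	1	0	0	2	2	1	0	1	0	1	1	0	0	0	0	1	1	1	1	0	0	1	1	1	1	0	1	1	0	0	1	0	1	1	1	1	0	0
S0004	1	0	0	0	0	0	0	1	1	0	1	1	1	0	0	0	1	1	0	0	0	0	0	1	2	1	0	1	1	0	0	1	1	0	0	1	1	0	0	1	0	1	0	1	0	1	0	1	0	0	1	1	1
S0005	2	1	2	0	0	2	0	1	0	1	1	1	0	0	1	1	1	2	2	1	1	1	1	0	1	1	0	1	0	1	1	0	1	1	1	0	1	0	0	0	0	0	0	1	2	1	0	0	0	0	0	0	0
S0006	1	0	0	0	0	0	0	1	1	1	0	0	1	0	1	2	2	1	1	2	2	0	0	0	0	0	0	1	1	1	1	1	1	0	1	0	1	0	0	0	0	0	0	1	0	0	1	1	1	0	1	1	1
S0007	2	1	0	1	1	1	0	0	0	0	0	0	0	0	0	1	0	0	0	0	1	1	0	1	2	0	0	1	1	1	0	0	1	0	1	1	1	0	0	0	0	1	1	2	1	1	2	1	1	1	1	0	0
S0008	0	1	1	1	1	1	0	1	0	1	0	0	0	0	0	1	0	0	0	1	0	0	0	0	2	1	1	2	0	0	0	0	1	0	1	1	2	0	0	0	0	1	1	2	2	2	1	1	0	0	0	0	1
S0009	1	1	2	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	1	1	1	1	0	0	1	1	0	1	0	0	1	1	1	0	1	0	1	0	0	0	1	0	1	2	1	0	1	0	2	1	0	0	0
S0010	0	0	0	0	0	1	0	0	0	0	1	0	1	0	0	0	0	0	2	1	0	1	1	1	1	1	1	1	0	0	0	0	0	0	1	0	1	0	0	0	0	1	2	0	0	0	1	1	1	1	0	0	0
S0011	1	1	0	0	1	0	0	1	1	0	0	1	1	0	0	1	1	1	1	1	0	1	2	0	1	1	1	1	0	0	1	1	0	1	1	0	0	1	0	0	0	0	0	2	1	1	1	1	0	0	0	0	0
S0012	2	1	1	1	0	0	0	0	0	0	0	0	1	0	1	1	2	1	1	1	1	2	0	0	1	0	0	1	0	0	0	1	0	0	0	1	1	1	0	1	2	1	1	0	0	0	0	1	1	0	0	0	0
S0013	1	1	1	2	1	0	0	1	1	1	1	1	0	0	1	1	0	1	0	0	1	2	0	0	0	0	0	1	1	1	1	1	0	0	0	0	1	1	0	0	0	1	0	0	0	0	0	1	1	0	0	1	1
S0014	0	0	0	0	1	1	0	1	1	1	0	0	1	0	0	0	1	0	0	1	0	1	1	1	0	0	0	0	1	2	0	0	0	0	0	0	1	1	0	1	0	1	1	1	2	1	0	0	0	1	0	0	1
S0015	2	0	0	0	0	0	0	1	1	2	0	0	0	0	1	1	1	0	1	0	1	0	0	0	0	0	1	1	0	0	1	1	1	1	0	0	2	0	0	0	0	2	0	1	1	1	0	1	2	2	1	0	0
S0016	1	0	0	0	0	1	1	2	1	0	0	0	1	0	0	0	2	1	1	0	0	1	1	0	1	0	0	2	1	1	0	1	1	0	1	1	1	2	0	0	0	0	1	0	0	1	1	1	1	1	1	0	0
S0017	2	0	0	0	0	1	0	0	0	0	0	2	2	0	1	1	1	0	0	0	1	1	1	1	1	0	1	0	0	0	2	2	0	1	1	0	1	0	1	0	0	1	1	1	0	2	0	0	0	0	1	1	0
S0018	0	0	1	1	1	0	1	0	0	1	1	0	0	1	1	1	1	0	0	0	1	2	0	0	1	0	0	1	0	0	1	1	0	1	1	1	0	1	1	0	0	1	1	0	0	1	1	1	1	0	0	0	1
S0019	1	0	1	0	0	0	0	0	0	2	0	0	1	0	1	0	2	2	1	1	1	1	1	1	1	1	0	1	0	0	1	2	0	0	0	0	0	0	0	0	0	0	1	2	0	0	1	1	1	2	0	1	0
S0020	2	1	1	0	1	1	1	1	1	1	0	0	0	0	0	0	0	1	1	2	1	0	0	0	0	0	0	1	0	0	1	0	0	0	0	0	2	1	0	0	0	1	1	1	0	0	1	1	0	1	0	0	0
S0021	2	0	1	0	1	1	0	0	0	0	0	1	1	0	0	0	1	0	1	1	0	0	0	0	1	1	0	2	1	1	1	1	1	2	0	0	1	1	1	0	0	1	0	1	0	0	1	1	1	2	2	1	0
S0022	1	1	1	0	0	0	1	1	0	1	0	1	0	0	0	1	1	1	0	1	1	1	0	0	0	0	1	1	2	0	0	0	0	0	1	0	1	1	0	0	0	0	1	2	2	1	0	1	1	0	0	1	1
S0023	0	0	0	1	1	0	0	1	0	1	0	0	0	0	0	0	0	0	1	1	0	1	0	0	1	0	0	0	1	1	1	2	0	0	0	0	1	0	0	0	0	2	1	0	2	1	0	0	1	1	1	0	0
S0024	0	0	1	1	1	1	0	1	1	1	0	0	1	0	0	1	2	2	2	0	1	1	0	0	2	0	0	1	2	2	1	1	0	1	1	1	1	1	0	2	1	1	2	2	1	0	0	0	1	1	1	1	0
S0025	1	2	0	1	0	0	0	1	1	1	0	0	2	1	0	1	0	0	1	0	0	1	0	0	1	1	1	0	0	0	1	0	1	0	1	1	0	0	0	0	0	2	0	2	0	0	1	1	1	1	0	0	0
S0026	1	0	1	2	0	0	0	1	0	0	0	0	1	1	1	0	0	0	1	0	1	1	1	0	1	0	1	1	0	1	0	2	1	0	0	0	1	1	1	0	0	0	1	0	0	0	0	2	0	1	1	1	0
S0027	2	0	0	1	0	0	0	0	1	0	0	0	1	0	0	1	1	0	0	0	0	1	1	0	0	0	0	1	1	0	0	1	0	0	1	0	1	2	0	0	0	0	1	1	1	2	0	1	1	0	1	0	0
S0028	2	1	2	0	0	1	1	0	0	0	0	0	1	0	0	0	1	1	1	1	2	2	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	1	0	0	1	1	1	0	1
S0029	2	0	0	0	0	0	0	1	1	1	0	1	1	0	0	1	1	1	1	0	0	1	0	2	0	0	0	2	0	0	1	1	0	0	1	1	1	0	0	0	0	1	1	1	0	0	1	1	1	1	0	0	1
S0030	2	1	0	0	0	1	0	1	0	0	0	0	0	0	1	2	0	0	1	0	1	0	0	1	1	0	0	2	1	1	1	1	0	1	0	0	1	1	0	0	0	0	0	2	2	2	1	0	0	2	0	0	1
S0031	1	0	0	0	1	1	0	0	0	1	0	0	1	0	0	1	0	0	0	0	0	0	0	0	1	0	0	0	1	0	1	2	1	0	0	0	0	0	0	0	1	0	1	1	0	2	0	0	1	1	1	0	1
S0032	1	0	0	0	1	0	0	1	1	1	0	0	1	0	0	0	2	1	1	1	1	2	0	0	0	1	1	2	2	2	1	1	0	1	1	0	1	0	0	0	0	2	1	1	0	0	1	1	1	0	1	0	1
S0033	1	0	0	0	1	2	0	0	0	1	0	1	1	0	0	0	1	1	1	0	0	0	0	0	0	0	0	1	0	0	0	2	0	0	0	0	1	0	1	1	0	0	1	1	2	1	2	1	1	1	1	0	0
S0034	1	0	1	0	1	0	0	0	0	1	0	0	1	0	0	0	1	0	1	1	1	1	2	0	1	1	2	0	0	1	0	0	0	0	0	0	1	0	0	0	0	2	1	2	1	1	0	1	2	2	0	1	0
S0035	1	0	0	0	1	1	0	0	0	2	0	0	0	0	0	0	1	1	1	0	2	0	0	0	2	2	0	1	1	1	2	2	1	1	0	0	2	0	0	0	0	0	0	2	1	1	1	0	1	1	1	0	1
S0036	1	1	1	1	1	1	0	0	0	0	0	0	0	0	0	0	1	0	2	2	0	2	0	0	1	1	0	1	2	1	0	0	0	0	1	1	2	1	0	0	0	0	0	1	0	0	1	1	1	1	2	1	0
S0037	2	0	0	0	0	0	0	1	0	0	1	1	0	1	1	1	0	0	0	1	2	2	0	0	1	0	0	1	1	1	0	0	0	0	1	0	0	0	1	1	0	2	1	1	0	0	1	0	0	0	2	1	1
S0038	1	1	0	1	0	1	1	1	1	1	0	0	0	0	0	0	0	0	1	1	0	1	1	0	0	0	1	1	0	1	1	1	0	0	1	0	1	0	0	0	0	1	1	0	0	0	0	0	1	1	1	1	0
S0039	0	0	2	0	0	0	0	0	0	1	1	1	1	0	0	0	0	1	1	1	0	1	0	0	0	0	0	2	0	1	0	0	0	0	1	1	2	0	0	1	1	1	1	1	1	1	0	1	0	0	1	0	0
S0040	1	0	0	1	1	1	0	1	1	1	0	0	0	0	0	1	1	1	1	0	0	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	1	1	1	0	0
S0041	2	0	1	0	0	0	1	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	1	0	0	2	1	0	0	0	2	0	1	0	1	0	0	1	1	0	0	0	1	0	0	0
S0042	1	1	1	0	0	0	0	1	1	1	0	0	0	0	1	1	2	2	0	1	0	0	0	0	0	0	0	1	0	0	0	2	2	2	0	0	1	0	0	0	0	0	0	1	1	0	1	1	0	2	2	1	1
S0043	1	0	0	1	0	2	2	1	1	1	0	0	1	0	0	0	0	0	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	1	2	1	1	0	1	2	1	1	1	1	2	1	2	1	0	0
S0044	2	0	1	0	0	1	0	0	0	1	0	0	0	0	0	0	0	0	0	0	1	0	0	0	1	0	0	2	0	0	1	1	1	1	0	0	0	0	0	0	1	0	0	2	2	1	0	2	1	0	0	0	1
S0045	2	1	1	0	1	1	0	0	0	1	0	0	1	0	1	2	0	0	1	0	0	0	1	0	0	0	1	1	1	1	0	0	0	0	2	0	1	0	0	0	1	1	1	2	1	2	1	0	0	0	0	0	1
S0046	2	1	1	1	1	1	0	1	0	1	0	2	2	0	0	0	0	1	1	1	0	2	0	0	1	0	0	1	1	0	1	1	1	1	1	0	2	1	0	0	0	1	2	2	1	1	1	0	1	0	1	0	0
S0047	0	0	0	1	0	1	1	1	0	0	1	1	2	0	1	0	1	1	1	2	1	2	2	1	0	0	0	0	2	1	1	2	1	1	0	0	2	1	1	0	0	0	1	0	0	0	0	1	0	1	0	0	0
S0048	1	1	0	1	0	0	1	1	0	1	1	0	0	0	0	0	2	2	2	0	0	1	1	1	2	0	0	1	1	2	0	0	0	1	0	0	1	1	1	1	0	2	1	0	0	0	0	0	1	1	1	1	0
S0049	2	1	0	0	0	0	0	0	0	1	0	0	0	0	0	0	1	2	2	0	1	1	0	0	0	1	0	2	2	2	1	1	0	0	0	0	0	1	1	2	0	1	1	0	2	0	1	1	1	1	1	1	0
S0050	1	0	0	0	0	0	0	0	0	1	1	1	2	0	0	0	1	0	0	0	1	0	0	0	1	0	0	1	1	2	1	1	1	2	1	1	1	0	0	1	0	1	0	0	1	1	0	0	1	1	0	0	0
S0051	1	1	0	0	0	1	0	0	0	0	1	1	2	0	1	0	1	1	2	0	1	0	0	0	0	0	0	0	2	1	1	1	0	0	2	0	2	1	0	0	1	0	0	0	0	0	0	0	0	0	0	0	1
S0052	1	0	1	0	1	0	0	0	0	1	0	0	1	0	0	1	0	1	2	1	1	1	1	0	1	1	0	1	1	0	0	0	0	1	1	1	1	0	0	0	0	0	1	1	0	0	0	0	0	0	0	1	0
S0053	1	0	0	0	1	2	0	0	0	0	0	0	0	1	1	0	0	0	0	1	1	1	1	1	0	0	0	0	0	1	0	2	1	1	0	0	1	2	1	1	0	0	0	1	1	1	1	1	0	1	0	0	1
S0054	1	1	1	1	1	1	0	0	1	1	1	0	0	2	1	1	0	0	0	0	0	2	1	0	0	0	0	1	1	1	0	0	0	0	1	0	0	1	0	0	0	0	0	1	1	2	1	0	1	1	0	0	0
S0055	1	0	0	1	1	1	0	1	0	1	0	0	1	0	0	0	0	0	1	1	1	2	0	0	0	0	1	1	0	1	0	0	0	0	0	0	0	0	0	0	0	0	1	0	1	1	0	2	2	1	1	1	1
S0056	1	1	2	1	1	0	0	0	0	0	1	0	0	0	0	0	2	1	0	0	0	0	0	0	1	0	0	1	2	2	0	1	1	0	1	1	1	0	0	0	0	0	1	1	0	0	0	0	0	1	1	0	2
S0057	2	2	1	0	0	0	0	0	1	1	0	0	0	0	0	1	0	0	0	1	0	0	0	0	0	0	1	1	1	0	0	1	1	1	1	1	1	1	1	0	0	1	0	0	1	1	0	1	0	0	1	0	0
S0058	1	0	1	2	1	0	0	1	0	0	0	1	2	1	1	2	2	0	1	1	1	2	0	0	1	1	0	0	0	1	1	1	0	0	1	1	0	1	1	1	1	1	0	2	1	0	1	0	1	1	1	1	0
S0059	0	0	0	1	0	1	0	1	1	1	1	1	0	0	0	1	0	0	0	1	1	1	1	0	0	1	1	2	1	1	0	1	0	0	0	0	0	1	0	0	0	1	0	1	1	1	0	1	1	2	0	0	0
S0060	2	1	1	1	2	1	1	0	0	0	1	0	0	0	0	0	1	0	1	0	1	2	2	1	1	1	0	1	1	1	0	0	0	0	0	0	1	1	0	0	1	1	0	1	2	1	0	0	0	0	0	0	0
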