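sample_id	dose_mg_per_day
S0001	3.767520
S0002	1.547254
S0003	7.174153
S0004	5.078543
S0005	5.766967
S0006	8.302636
S0007	4.671161
S0008	10.510039
S0009	5.152443
S0010	4.024711
S0011	5.356074
S0012	3.887808
S0013	10.353404
S0014	7.994010
S0015	4.026665
S0016	5.750508
S0017	2.624566
S0018	7.196069
S0019	3.588443
S0020	7.495758
S0021	2.370355
S0022	4.680591
S0023	1.638741
S0024	8.631559
S0025	6.648584
S0026	7.873263
S0027	5.268612
S0028	6.613821
S0029	2.916845
S0030	3.608330
S0031	5.146177
S0032	4.134103
S0033	3.446354
S0034	3.457626
S0035	6.103908
S0036	10.309888
S0037	1.262460
S0038	10.437801
S0039	3.689242
S0040	10.514672
S0041	3.803686
S0042	2.855538
S0043	14.120033
S0044	5.647740
S0045	3.542505
S0046	6.912195
S0047	6.689069
S0048	6.506796
S0049	2.876560
S0050	1.036512
S0051	7.310471
S0052	4.378744
S0053	6.097214
S0054	9.103083
S0055	4.947978
S0056	2.474367
S0057	3.049417
S0058	0.703988
S0059	7.729056
S0060	7.660872
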