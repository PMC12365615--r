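pt	soc
pt_0001	soc_01
pt_0002	soc_02
pt_0003	soc_03
pt_0004	soc_04
pt_0005	soc_05
pt_0006	soc_06
pt_0007	soc_07
pt_0008	soc_08
pt_0009	soc_01
pt_0010	soc_02
pt_0011	soc_03
pt_0012	soc_04
pt_0013	soc_05
pt_0014	soc_06
pt_0015	soc_07
pt_0016	soc_08
pt_0017	soc_01
pt_0018	soc_02
pt_0019	soc_03
pt_0020	soc_04
pt_0021	soc_05
pt_0022	soc_06
pt_0023	soc_07
pt_0024	soc_08
pt_0025	soc_01
pt_0026	soc_02
pt_0027	soc_03
pt_0028	soc_04
pt_0029	soc_05
pt_0030	soc_06
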