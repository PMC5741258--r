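marker	A001	A002	A003	A004
M00001	2	2	2	2
M00002	2	2	2	2
M00003	2	2	2	2
M00004	2	2	2	2
M00005	2	2	0	2
M00006	2	2	2	2
M00007	2	2	2	2
M00008	2	2	0	0
M00009	0	2	2	2
M00010	2	2	2	2
M00011	2	2	0	2
M00012	2	2	2	2
M00013	2	2	2	2
M00014	0	2	2	2
M00015	2	2	2	2
M00016	2	2	2	2
M00017	2	2	2	2
M00018	2	0	0	2
M00019	2	0	2	0
M00020	2	2	2	2
M00021	2	0	0	2
M00022	2	2	2	2
M00023	2	2	2	2
M00024	2	2	2	2
M00025	2	2	2	0
M00026	2	2	2	2
M00027	2	2	2	2
M00028	2	2	2	2
M00029	2	0	2	2
M00030	2	0	0	2
M00031	2	2	0	2
M00032	2	2	2	2
M00033	2	2	2	2
M00034	2	2	2	2
M00035	2	2	2	2
M00036	2	2	2	2
M00037	2	2	2	2
M00038	2	2	2	2
M00039	2	2	2	0
M00040	2	2	2	0
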