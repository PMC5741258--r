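individual	M00001	M00002	M00003	M00004	M00005	M00006	M00007	M00008	M00009	M00010	M00011	M00012	M00013	M00014	M00015	M00016	M00017	M00018	M00019	M00020	M00021	M00022	M00023	M00024	M00025	M00026	M00027	M00028	M00029	M00030	M00031	M00032	M00033	M00034	M00035	M00036	M00037	M00038	M00039	M00040
A_P002_D02	2	2	2	2	2	2	2	0	2	2	2	2	2	2	2	2	2	2	0	2	0	2	2	2	2	2	2	2	0	0	2	2	2	2	2	2	2	2	2	0
A_P001_D02	2	2	2	2	0	2	2	0	2	2	0	2	2	2	2	2	2	0	2	2	0	2	2	2	2	2	2	2	2	0	0	2	2	2	2	2	2	2	2	2
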