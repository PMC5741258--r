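marker	ref_reads	total_reads
M00001	3	3
M00002	2	2
M00003	2	2
M00004	5	5
M00005	0	2
M00006	0	0
M00007	1	1
M00008	0	2
M00009	2	2
M00010	1	1
M00011	2	3
M00012	5	5
M00013	2	2
M00014	2	2
M00015	2	2
M00016	3	3
M00017	2	2
M00018	0	1
M00019	1	2
M00020	1	1
M00021	0	2
M00022	3	3
M00023	0	0
M00024	5	5
M00025	0	0
M00026	0	0
M00027	0	0
M00028	3	3
M00029	2	3
M00030	0	0
M00031	0	0
M00032	3	3
M00033	5	5
M00034	1	1
M00035	2	2
M00036	2	2
M00037	1	1
M00038	1	1
M00039	2	2
M00040	0	1
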