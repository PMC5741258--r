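marker	chrom	pos_cM
M00001	chr01	0.154235083609819
M00002	chr01	5.65995827317238
M00003	chr01	7.30660706758499
M00004	chr01	8.72571259737015
M00005	chr01	15.393483787775
M00006	chr01	22.3170510679483
M00007	chr01	23.140988945961
M00008	chr01	25.7717823795974
M00009	chr01	26.2075161747634
M00010	chr01	29.6059633791447
M00011	chr01	36.1679701879621
M00012	chr01	42.3330954089761
M00013	chr01	57.2422045841813
M00014	chr01	59.4241672195494
M00015	chr01	60.6237083300948
M00016	chr01	61.4826566912234
M00017	chr01	65.5565188452601
M00018	chr01	70.2017110958695
M00019	chr01	77.032562494278
M00020	chr01	78.4283667989075
M00021	chr02	2.42051910609007
M00022	chr02	5.12687526643276
M00023	chr02	5.56725392118096
M00024	chr02	6.18280814960599
M00025	chr02	14.87812358886
M00026	chr02	20.6273819878697
M00027	chr02	21.196836642921
M00028	chr02	26.4720430783927
M00029	chr02	35.218522567302
M00030	chr02	35.8257865905762
M00031	chr02	37.2655822895467
M00032	chr02	37.9989917762578
M00033	chr02	39.3574160151184
M00034	chr02	40.9006167203188
M00035	chr02	52.1152981743217
M00036	chr02	54.0087294392288
M00037	chr02	66.7296532541513
M00038	chr02	72.5695218704641
M00039	chr02	72.7995797805488
M00040	chr02	79.3821428157389
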