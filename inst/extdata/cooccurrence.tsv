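dui_a	dui_b	count
D002446	D003922	523
D002446	D003874	478
D002446	D013967	96
D002446	D001172	87
D002446	D008180	73
D002446	D009103	44
D002446	D012859	43
D002446	D000224	42
D002446	D001171	37
D002446	D019693	35
D002446	D006111	30
D002446	D005922	27
D002446	D009157	22
D002446	D016884	15
D002446	D016736	12
D002446	D900001	812
D002446	D900002	655
D002446	D900003	540
D002446	D900004	498
D002446	D900005	430
D002446	D900006	61
D002446	D900007	58
D002446	D900008	384
D002446	D900009	291
D002446	D900010	171
D002446	D900011	140
D002446	D900012	96
D002446	D900013	88
D002446	D900014	202
D002446	D900015	77
D002446	D900016	49
D002446	D900017	33
D002446	D900018	29
D002446	D900019	24
D002446	D900020	19
D003922	D900001	104
D013967	D900002	66
D900001	D900002	57
D900003	D900004	231
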