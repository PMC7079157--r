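value	age_min	age_max
0.459010833500755	3.75	4.25
0.468824212218952	3.6649	4.1649
0.53299901651757	3.5798	4.0798
0.590965787957857	3.4947	3.9947
0.619366152812747	3.4096	3.9096
0.541303408917273	3.3245	3.8245
0.58094985962887	3.2394	3.7394
0.609738629957105	3.1543	3.6543
0.603883001958518	3.0691	3.5691
0.61369022671777	2.984	3.484
0.582251263287086	2.8989	3.3989
0.596013937826715	2.8138	3.3138
0.660009458877022	2.7287	3.2287
0.594709840515233	2.6436	3.1436
0.632639812261863	2.5585	3.0585
0.632930295862779	2.4734	2.9734
0.624928018159842	2.3883	2.8883
0.645324425360408	2.3032	2.8032
0.634291096922371	2.2181	2.7181
0.497738924973719	2.133	2.633
0.517162176036212	2.0479	2.5479
0.522481609364179	1.9628	2.4628
0.548053220021645	1.8777	2.3777
0.452214661556241	1.7926	2.2926
0.458079397534296	1.7074	2.2074
0.348460796683991	1.6223	2.1223
0.386591949912583	1.5372	2.0372
0.388737759561388	1.4521	1.9521
0.365105985101742	1.367	1.867
0.355186533022109	1.2819	1.7819
0.318893393794136	1.1968	1.6968
0.34446126817468	1.1117	1.6117
0.305303194754147	1.0266	1.5266
0.274762988691477	0.9415	1.4415
0.319127798865222	0.8564	1.3564
0.298644875682703	0.7713	1.2713
0.245342354717922	0.6862	1.1862
0.293640983834922	0.6011	1.1011
0.367660274125374	0.516	1.016
0.329164232177256	0.4309	0.9309
0.371421021846111	0.3457	0.8457
0.362071099375183	0.2606	0.7606
0.271524647948875	0.1755	0.6755
0.374198037932183	0.0904	0.5904
0.388444496427663	0.0053	0.5053
0.394574243447755	0	0.4202
0.436715615301516	0	0.3351
0.379251839669875	0	0.25
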