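value	age_min	age_max
1173.59980851609	3.8	4.2
1186.61648987492	3.6974	4.0974
1035.7580604131	3.5949	3.9949
1283.7283717681	3.4923	3.8923
1066.53725722234	3.3897	3.7897
1099.33289496768	3.2872	3.6872
1183.14479526337	3.1846	3.5846
1083.07176010725	3.0821	3.4821
1247.45230431221	2.9795	3.3795
1088.37540870568	2.8769	3.2769
1150.38638428231	2.7744	3.1744
1199.11184543469	2.6718	3.0718
1004.9234572195	2.5692	2.9692
1087.34973017263	2.4667	2.8667
1129.17906858889	2.3641	2.7641
1176.09075803284	2.2615	2.6615
1030.78707233915	2.159	2.559
1104.08597123573	2.0564	2.4564
1055.88660700414	1.9538	2.3538
980.634764430354	1.8513	2.2513
1080.5597614818	1.7487	2.1487
1030.84286658384	1.6462	2.0462
1117.19018124206	1.5436	1.9436
989.74011888117	1.441	1.841
996.557613095026	1.3385	1.7385
1038.88881084733	1.2359	1.6359
1022.05884759359	1.1333	1.5333
1005.81946393185	1.0308	1.4308
927.578778469097	0.9282	1.3282
1007.8398398278	0.8256	1.2256
940.428931512125	0.7231	1.1231
1021.40700636373	0.6205	1.0205
920.480192965498	0.5179	0.9179
1021.41242721841	0.4154	0.8154
902.087069055401	0.3128	0.7128
961.372875895383	0.2103	0.6103
944.047223368097	0.1077	0.5077
959.74924352767	0.0051	0.4051
940.36443332031	0	0.3026
941.911374917141	0	0.2
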