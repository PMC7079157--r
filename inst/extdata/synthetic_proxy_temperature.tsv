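value	age_min	age_max
25.382094010771	3.8	4.2
24.9799379082197	3.6974	4.0974
23.7471669932077	3.5949	3.9949
25.1746739675083	3.4923	3.8923
25.1247974601942	3.3897	3.7897
23.966596637218	3.2872	3.6872
24.4885836388416	3.1846	3.5846
24.4983085958366	3.0821	3.4821
24.3710853575518	2.9795	3.3795
24.6374962304766	2.8769	3.2769
23.5971767085844	2.7744	3.1744
23.8814613746565	2.6718	3.0718
25.4378290835227	2.5692	2.9692
25.4791084137447	2.4667	2.8667
25.8714309915017	2.3641	2.7641
24.4824375372243	2.2615	2.6615
24.926064122578	2.159	2.559
24.5066663534911	2.0564	2.4564
24.4618638133996	1.9538	2.3538
24.9276302600045	1.8513	2.2513
23.6988734477465	1.7487	2.1487
24.6925413483734	1.6462	2.0462
24.5195820208893	1.5436	1.9436
24.8311155619643	1.441	1.841
25.2769797964699	1.3385	1.7385
24.5101442917155	1.2359	1.6359
25.2088260391243	1.1333	1.5333
24.7473207675381	1.0308	1.4308
24.4931549561911	0.9282	1.3282
24.3952328798114	0.8256	1.2256
24.4682306437466	0.7231	1.1231
23.834738399867	0.6205	1.0205
23.9652199696814	0.5179	0.9179
23.0855361340261	0.4154	0.8154
24.1210610889808	0.3128	0.7128
23.0535911954345	0.2103	0.6103
23.6422641037316	0.1077	0.5077
23.5984348792722	0.0051	0.4051
23.4016898360967	0	0.3026
24.095416109883	0	0.2
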