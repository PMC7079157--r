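value	age_min	age_max
508.946112363608	3.75	4.25
529.831799783416	3.6524	4.1524
470.926190573478	3.5549	4.0549
530.825511804428	3.4573	3.9573
500.795060444519	3.3598	3.8598
531.375788608795	3.2622	3.7622
549.529928400669	3.1646	3.6646
548.046100898073	3.0671	3.5671
608.764815251375	2.9695	3.4695
518.492776101449	2.872	3.372
546.315594787282	2.7744	3.2744
600.261752263653	2.6768	3.1768
564.899376894591	2.5793	3.0793
730.739544469994	2.4817	2.9817
764.771598012349	2.3841	2.8841
760.450919622252	2.2866	2.7866
738.083920304341	2.189	2.689
712.880328051229	2.0915	2.5915
879.055830341829	1.9939	2.4939
818.224044620599	1.8963	2.3963
920.81474793	1.7988	2.2988
1112.11039637278	1.7012	2.2012
1131.40172599302	1.6037	2.1037
1229.17655254962	1.5061	2.0061
1200.14207164079	1.4085	1.9085
1182.89232578719	1.311	1.811
1167.3992974223	1.2134	1.7134
1354.79895427031	1.1159	1.6159
1300.13508739469	1.0183	1.5183
1322.75404633522	0.9207	1.4207
1392.38843056829	0.8232	1.3232
1505.84663883857	0.7256	1.2256
1379.98664457696	0.628	1.128
1383.69247293082	0.5305	1.0305
1470.54761108732	0.4329	0.9329
1485.44073332919	0.3354	0.8354
1473.60463256979	0.2378	0.7378
1519.49711064846	0.1402	0.6402
1526.67287119555	0.0427	0.5427
1512.3481971406	0	0.4451
1487.359324859	0	0.3476
1466.3660198838	0	0.25
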