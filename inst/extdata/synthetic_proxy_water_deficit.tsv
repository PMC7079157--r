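value	age_min	age_max
235.434907623022	3.8	4.2
145.040628694508	3.6857	4.0857
226.678435965833	3.5714	3.9714
179.571032761487	3.4571	3.8571
265.514636818926	3.3429	3.7429
210.76888213554	3.2286	3.6286
304.178969659094	3.1143	3.5143
249.963702766612	3	3.4
236.202183687627	2.8857	3.2857
328.453277602021	2.7714	3.1714
284.205548787811	2.6571	3.0571
254.996510149622	2.5429	2.9429
337.287369178984	2.4286	2.8286
411.908727120034	2.3143	2.7143
362.424455820219	2.2	2.6
325.870935092937	2.0857	2.4857
321.777973451245	1.9714	2.3714
387.38828004653	1.8571	2.2571
339.129233583441	1.7429	2.1429
403.646198453508	1.6286	2.0286
322.280532716174	1.5143	1.9143
297.543284982861	1.4	1.8
330.816278821325	1.2857	1.6857
383.5073988925	1.1714	1.5714
380.948202620865	1.0571	1.4571
349.966354807192	0.9429	1.3429
399.387682419976	0.8286	1.2286
338.255845231224	0.7143	1.1143
408.217624217867	0.6	1
437.173202535603	0.4857	0.8857
442.268076395845	0.3714	0.7714
423.684840442059	0.2571	0.6571
461.466356870606	0.1429	0.5429
520.520071251966	0.0286	0.4286
477.522811352419	0	0.3143
449.714161504192	0	0.2
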