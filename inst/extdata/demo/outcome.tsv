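rsid	effect_allele	other_allele	eaf	beta	se	pvalue
rs00001	T	C	0.4267945725470782	-0.019906143018034509	0.042644698247313498	0.6406497229836996
rs00002	A	G	0.79314312022179367	0.027804932062376032	0.033404878396540882	0.40520497087195512
rs00003	A	C	0.81347127594053747	0.0098488760772195635	0.031136054061353211	0.75176159539138199
rs00004	A	G	0.64248805083334448	0.039023790360798442	0.04624335213797167	0.39873706521332847
rs00005	T	G	0.76537013798952103	-0.036703622957569099	0.033037919220514599	0.26658796171528604
rs00006	G	A	0.85873606689274307	0.026313724169369404	0.033204103296156973	0.42807845476588258
rs00007	G	A	0.45737485364079478	-0.017477520755055077	0.022458705001045021	0.43644700882906728
rs00008	A	C	0.78646307438611984	0.0086597247306711839	0.021038579102605582	0.68062407477104681
rs00009	C	T	0.77289234027266507	-0.083552937974708891	0.047859559452626856	0.080846731280471554
rs00010	T	G	0.72304721083492041	0.032683022500093556	0.028836988916154951	0.25705826099735446
rs00011	G	A	0.54500075355172151	0.0017688404841976028	0.035576728624291717	0.96034629042625852
rs00012	A	G	0.79478200022131207	-0.032273635824766847	0.027091892748139799	0.23354939248190876
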