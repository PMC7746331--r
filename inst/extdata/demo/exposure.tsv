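rsid	effect_allele	other_allele	eaf	beta	se	pvalue
rs00001	T	C	0.4267945725470782	0.066578739305946433	0.0032320161911193281	2.7583911841832176e-94
rs00002	A	G	0.79314312022179367	0.032595490379030069	0.0024202425670810045	2.4176903823841514e-41
rs00003	C	A	0.18652872405946255	0.052902001958495398	0.002016303550451994	1.0026567764928785e-151
rs00004	G	A	0.35751194916665552	0.05076063763591767	0.0038052164469845593	1.359138267049461e-40
rs00005	G	T	0.23462986201047897	0.044834662115235339	0.0047330303818453106	2.7265495992437407e-21
rs00006	A	G	0.14126393310725691	0.044235050843176589	0.0025260883518494663	1.1751300037926287e-68
rs00007	A	G	0.54262514635920522	0.035994839366452695	0.0041935622396413238	9.2144296371013671e-18
rs00008	C	A	0.21353692561388016	0.029075760721176833	0.0020484716289211067	9.9970713821050034e-46
rs00009	T	C	0.22710765972733499	0.053521800457701954	0.0037583471487741917	5.1151821078673359e-46
rs00010	T	G	0.72304721083492041	0.041122095749792392	0.0032774552851915361	4.1307311127318443e-36
rs00011	A	G	0.45499924644827849	0.044900302842891482	0.002631472932873294	2.807569475974391e-65
rs00012	G	A	0.20521799977868796	0.037427964687595794	0.0034316003250423818	1.068913943253852e-27
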