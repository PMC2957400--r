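allele	nearest	auc	rmse_kcal	corr
DRB1*0101	DRB1*1501	0.646	1.86	0.306
DRB1*0301	DRB1*1302	0.628	1.89	0.170
DRB1*0401	DRB1*0405	0.656	1.93	0.348
DRB1*0404	DRB1*0401	0.745	1.46	0.483
DRB1*0405	DRB1*0401	0.732	1.43	0.403
DRB1*0701	DRB1*0901	0.681	1.72	0.382
DRB1*0802	DRB1*1101	0.793	1.58	0.505
DRB1*0901	DRB1*0701	0.671	1.81	0.388
DRB1*1101	DRB1*1302	0.628	1.89	0.264
DRB1*1302	DRB1*1101	0.646	1.85	0.302
DRB1*1501	DRB1*0101	0.670	2.11	0.363
DRB3*0101	DRB1*0301	0.654	1.59	0.322
DRB4*0101	DRB1*0101	0.665	2.05	0.295
DRB5*0101	DRB1*0101	0.736	2.05	0.433
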