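allele	nearest	auc	rmse_kcal	corr
DPB1*0101	DPB1*0501	0.883	1.13	0.660
DPB1*0201	DPB1*0402	0.863	1.13	0.669
DPB1*0401	DPB1*0402	0.872	1.12	0.633
DPB1*0402	DPB1*0201	0.824	1.20	0.623
DPB1*0501	DPB1*0101	0.876	1.10	0.661
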