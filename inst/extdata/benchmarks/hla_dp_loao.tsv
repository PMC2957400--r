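allele	auc	rmse_kcal	corr	n
DPB1*0101	0.892	2.74	0.706	481
DPB1*0201	0.890	1.99	0.718	474
DPB1*0401	0.903	0.960	0.730	552
DPB1*0402	0.901	0.981	0.698	537
DPB1*0501	0.871	1.01	0.628	475
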