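allele	auc	rmse_kcal	corr	auc_netmhciipan	corr_netmhciipan	auc_tepitope	n
DRB1*0101	0.801	1.33	0.619	0.778	0.570	0.720	5166
DRB1*0301	0.751	1.36	0.438	0.746	0.449	0.664	1020
DRB1*0401	0.763	1.56	0.534	0.775	0.598	0.716	1024
DRB1*0404	0.835	1.33	0.623	0.852	0.684	0.770	663
DRB1*0405	0.808	1.28	0.566	0.808	0.597	0.759	630
DRB1*0701	0.817	1.51	0.620	0.825	0.655	0.761	853
DRB1*0802	0.786	1.45	0.523	0.841	0.631	0.766	420
DRB1*0901	0.674	2.01	0.380	0.653	0.388	NA	530
DRB1*1101	0.819	1.46	0.603	0.799	0.588	0.721	950
DRB1*1302	0.698	1.68	0.365	0.658	0.351	0.652	498
DRB1*1501	0.729	1.57	0.513	0.738	0.535	0.686	934
DRB3*0101	0.813	1.10	0.603	0.716	0.444	NA	549
DRB4*0101	0.746	1.61	0.508	0.724	0.469	NA	446
DRB5*0101	0.788	1.60	0.543	0.831	0.633	0.680	924
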