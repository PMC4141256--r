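gene	PT001	PT002	PT003	PT004	PT005	PT006	PT007	PT008	PT009	PT010	PT011	PT012
G0001	5.6712	4.8794	8.6802	8.01	5.1002	5.8383	7.1533	6.8728	7.0605	6.402	7.2837	6.455
G0002	10.1939	12.1447	11.9055	12.7832	11.9741	11.8061	11.6984	11.5956	11.3176	10.5996	11.2158	10.7726
G0003	6.5265	8.6618	8.5811	9.1738	7.5585	8.041	8.1449	9.3634	9.8813	7.8415	7.4383	7.4874
G0004	11.1126	11.5758	11.7662	11.0454	12.5067	10.6871	11.0054	12.5167	12.1171	11.3404	12.1401	10.297
G0005	10.0422	10.5919	11.9221	9.8393	10.599	13.5111	10.4577	9.4598	10.5382	8.8331	11.6412	10.4542
G0006	5.8386	7.8446	7.3336	6.7896	8.7346	6.8518	6.8496	5.985	7.2614	6.4484	6.1156	5.8798
G0007	11.0285	10.2778	12.3148	12.4831	10.2536	11.0927	11.2221	12.8889	11.0718	12.0609	11.1793	11.5908
G0008	6.6745	5.9348	6.3992	6.2669	6.9036	6.0874	6.1436	7.0582	8.5616	4.316	7.2575	7.076
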