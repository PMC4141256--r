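sample	time	event	age	male	smoking	stage
PT001	114.5	1	64.9	0	1	2
PT002	11.45	1	62.6	0	0	1
PT003	10.05	1	66.3	1	1	2
PT004	41.15	0	61.7	0	1	3
PT005	15.43	1	60.8	0	1	1
PT006	104.71	1	48.3	1	1	1
PT007	15.33	0	61.5	0	1	3
PT008	29.89	1	71.2	0	0	3
PT009	38.4	1	72.5	0	1	2
PT010	2.32	0	59.9	1	0	2
PT011	15.62	1	67.8	1	0	2
PT012	27.16	0	66.2	1	1	1
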