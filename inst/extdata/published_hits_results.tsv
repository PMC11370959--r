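condition	probe_id	beta	ci_low	ci_high	p	chr	pos	gene
dysmenorrhea	cg08142094	-0.036	-0.050	-0.022	1.02e-6	16	85731256	
dysmenorrhea	cg23012731	-0.008	-0.011	-0.005	3.53e-6	1	33438978	
dysmenorrhea	cg21802726	-0.002	-0.003	-0.004	3.74e-4	20	33735257	EDEM2
dysmenorrhea	cg04583842	-0.034	-0.053	-0.016	4.17e-4	16	88103117	BANP
dysmenorrhea	cg22603569	-0.017	-0.029	-0.005	6.14e-3	19	3388047	NFIC
dysmenorrhea	cg04737758	0.042	0.025	0.058	1.13e-6	14	74824136	
dysmenorrhea	cg15017604	0.026	0.015	0.037	9.39e-6	11	1361518	
hmb	cg24196053	-0.010	-0.014	-0.006	1.50e-5	4	1736433	TACC3
hmb	cg11465939	-0.029	-0.042	-0.015	6.04e-5	22	23923462	IGLL1
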