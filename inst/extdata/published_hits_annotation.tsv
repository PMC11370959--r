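probe_id	chr	pos	gene	class	detection_fail	chen_flag
cg08142094	16	85731256		cpg	0	0
cg23012731	1	33438978		cpg	0	0
cg21802726	20	33735257	EDEM2	cpg	0	0
cg04583842	16	88103117	BANP	cpg	0	0
cg22603569	19	3388047	NFIC	cpg	0	0
cg04737758	14	74824136		cpg	0	0
cg15017604	11	1361518		cpg	0	0
cg24196053	4	1736433	TACC3	cpg	0	0
cg11465939	22	23923462	IGLL1	cpg	0	0
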