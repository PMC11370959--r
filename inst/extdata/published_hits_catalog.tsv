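cpg	gene	trait	study_id	p
cg21802726		Rheumatoid arthritis	S0001	1e-07
cg04583842		Smoking	S0002	1e-07
cg04583842		Gestational age	S0003	1e-07
cg04583842		BMI	S0004	1e-07
cg04583842		CRP	S0005	1e-07
cg04583842		Mortality	S0006	1e-07
cg22603569		Fetal vs adult liver	S0007	1e-07
cg22603569		Gestational age	S0008	1e-07
cg22603569		Alcohol consumption	S0009	1e-07
cg22603569		Hypertensive disorders of pregnancy (HDPs)	S0010	1e-07
cg11465939		Fetal vs adult liver	S0011	1e-07
cg11465939		Smoking	S0012	1e-07
cg11465939		Gestational age	S0013	1e-07
cg90000001	EDEM2	Rheumatoid arthritis	S0101	1e-07
cg90000002	EDEM2	Ischaemic stroke	S0102	1e-07
cg90000003	EDEM2	Primary Sjögren's syndrome	S0103	1e-07
cg90000004	EDEM2	HIV infection	S0104	1e-07
cg90000011	BANP	Clear cell renal carcinoma	S0111	1e-07
cg90000012	BANP	Fetal vs adult liver	S0112	1e-07
cg90000013	BANP	HIV infection	S0113	1e-07
cg90000014	BANP	Smoking	S0114	1e-07
cg90000015	BANP	Age	S0115	1e-07
cg90000016	BANP	Gestational age	S0116	1e-07
cg90000017	BANP	Rheumatoid arthritis	S0117	1e-07
cg90000018	BANP	BMI	S0118	1e-07
cg90000019	BANP	Primary Sjögren's syndrome	S0119	1e-07
cg90000020	BANP	Chronic kidney disease	S0120	1e-07
cg90000021	BANP	CRP	S0121	1e-07
cg90000022	BANP	Sex	S0122	1e-07
cg90000023	BANP	Mortality	S0123	1e-07
cg90000024	BANP	Child abuse	S0124	1e-07
cg90000025	BANP	Melanoma	S0125	1e-07
cg90000026	BANP	Alcohol consumption	S0126	1e-07
cg90000027	BANP	Crohn's disease	S0127	1e-07
cg90000028	BANP	Pre-eclampsia	S0128	1e-07
cg90000029	BANP	Air pollution exposure	S0129	1e-07
cg90000030	BANP	Maternal urinary arsenic	S0130	1e-07
cg90000031	BANP	Cognitive ability	S0131	1e-07
cg90000032	BANP	Total cholesterol	S0132	1e-07
cg90000033	BANP	Chylomicrons and extremely large vLDLs	S0133	1e-07
cg90000034	BANP	FASD	S0134	1e-07
cg90000041	NFIC	Fetal vs adult liver	S0141	1e-07
cg90000042	NFIC	Gestational age	S0142	1e-07
cg90000043	NFIC	Smoking	S0143	1e-07
cg90000044	NFIC	Pancreatic ductal adenocarcinoma	S0144	1e-07
cg90000045	NFIC	Aging	S0145	1e-07
cg90000046	NFIC	Rheumatoid arthritis	S0146	1e-07
cg90000047	NFIC	Cleft lip vs palate	S0147	1e-07
cg90000048	NFIC	Age	S0148	1e-07
cg90000049	NFIC	HIV infection	S0149	1e-07
cg90000050	NFIC	Alcohol consumption	S0150	1e-07
cg90000051	NFIC	Primary Sjögren's syndrome	S0151	1e-07
cg90000052	NFIC	Sex	S0152	1e-07
cg90000053	NFIC	Time spent sitting	S0153	1e-07
cg90000054	NFIC	Pre-eclampsia	S0154	1e-07
cg90000055	NFIC	HDPs	S0155	1e-07
cg90000056	NFIC	Crohn's disease	S0156	1e-07
cg90000061	TACC3	Clear cell renal carcinoma	S0161	1e-07
cg90000062	TACC3	Gestational age	S0162	1e-07
cg90000063	TACC3	HIV infection	S0163	1e-07
cg90000064	TACC3	Crohn's disease	S0164	1e-07
cg90000065	TACC3	Alzheimer's disease	S0165	1e-07
cg90000066	TACC3	Pre-eclampsia	S0166	1e-07
cg90000067	TACC3	Total cholesterol	S0167	1e-07
cg90000071	IGLL1	Clear cell renal carcinoma	S0171	1e-07
cg90000072	IGLL1	Fetal vs adult liver	S0172	1e-07
cg90000073	IGLL1	Gestational age	S0173	1e-07
cg90000074	IGLL1	HIV infection	S0174	1e-07
cg90000075	IGLL1	Primary Sjögren's syndrome	S0175	1e-07
cg90000076	IGLL1	Smoking	S0176	1e-07
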