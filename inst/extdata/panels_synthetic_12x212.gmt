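Cell_Cycle	synthetic stand-in panel (15 genes)	595	898	1019	1021	1017	983	891	890	5925	1869	1026	1027	1029	1111	11200
Wnt	synthetic stand-in panel (20 genes)	7471	89780	1499	324	8312	8313	2932	4041	4040	8321	8324	6932	6934	51176	22943	27122	6422	6423	11197	1855
Notch	synthetic stand-in panel (16 genes)	4851	4853	4854	4855	182	3714	28514	10683	54567	3280	23462	3516	9794	6868	5663	8650
PI3K	synthetic stand-in panel (18 genes)	5290	5291	5293	5295	5296	5728	207	208	10000	2475	253260	57521	7248	7249	6009	5170	2309	8821
Purine_Biosynthesis	synthetic stand-in panel (22 genes, 9 shared with Pyrimidine)	5471	2618	5198	10606	158	471	159	3614	3615	8833	3251	353	100	5631	5634	6240	6241	50484	4830	4831	22978	4907
Pyrimidine_Biosynthesis	synthetic stand-in panel (19 genes, 9 shared with Purine)	790	1723	7372	51727	1503	56474	1841	7298	7083	7371	5631	5634	6240	6241	50484	4830	4831	22978	4907
TP53	synthetic stand-in panel (17 genes)	7157	4193	4194	8626	7161	472	545	581	27113	5366	7158	7874	8493	2810	57103	1647	64393
TGF_beta	synthetic stand-in panel (18 genes)	7040	7042	7043	7046	7048	7049	4087	4088	4089	4092	90	92	650	652	657	659	3624	4052
Hippo	synthetic stand-in panel (20 genes)	10413	25937	7003	8463	7005	7004	9113	26524	6788	6789	60485	55233	92597	4771	23286	154796	154810	51421	57551	122786
Myc	synthetic stand-in panel (14 genes)	4609	4613	4610	4149	4084	4601	83463	10608	4335	23269	6945	22877	51085	4150
TCA_Cycle	synthetic stand-in panel (24 genes)	1431	48	50	3417	3418	3419	3420	3421	4967	1743	1738	8802	8801	8803	6389	6390	6391	6392	2271	4190	4191	5091	5160	5162
Pentose_Phosphate	synthetic stand-in panel (18 genes)	2539	25796	5226	6120	22934	7086	8277	84076	6888	9563	5236	55276	23729	51071	5635	5636	2821	5211
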