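dinucleotide	P001	P002	P003	P004	P005	P006	P007	P008	P009	P010	P011	P012	P013	P014	P015	P016	P017	P018	P019	P020	P021	P022	P023	P024	P025	P026	P027	P028	P029	P030	P031	P032	P033	P034	P035	P036	P037	P038	P039	P040	P041	P042	P043	P044	P045	P046	P047	P048	P049	P050	P051	P052	P053	P054	P055	P056	P057	P058	P059	P060	P061	P062	P063	P064	P065
AA	8.0809	2.7821	-1.0444	6.4315	-1.7731	8.0081	1.4063	7.0774	-5.7871	4.5903	8.2632	2.3171	4.4448	5.9205	2.6153	3.7848	9.0289	10.0224	5.3219	1.7662	-2.3812	5.0937	1.8047	5.3095	8.7179	9.0488	7.5417	0.037	11.0924	6.8765	6.8112	2.5591	2.0119	-1.5346	-0.8809	4.6845	7.1195	-0.2005	-0.602	8.2648	-1.6024	11.4315	5.2803	-2.5074	7.785	1.1233	6.6756	4.3498	1.6793	-1.3233	-1.2795	6.1168	-4.5225	2.4421	3.2667	7.9758	8.6736	0.1219	7.6495	3.509	0.4824	3.5017	1.0254	6.7322	6.9563
AC	8.1434	2.7442	-1.6421	2.2997	-1.1708	8.6357	4.0603	7.1276	1.2894	5.8108	9.0974	5.2948	4.6531	6.6715	2.629	1.7463	6.6093	7.8269	4.3476	1.79	-1.3987	3.4579	4.6885	4.8774	4.5956	8.7026	8.1299	3.7715	7.9796	7.2434	6.7874	2.783	-0.8216	-0.6593	2.7905	5.31	7.3227	-1.4205	-0.7849	7.8116	-0.1074	9.9745	5.7956	-0.6212	6.2467	-1.2111	7.2668	4.7046	2.2443	-1.1774	-1.4745	5.8034	-4.1514	1.7753	2.9058	7.0019	9.417	0.2205	7.6532	5.4489	-2.0922	4.1015	-0.2036	7.7629	7.0826
AG	10.7424	0.9531	-1.9229	4.3441	-1.6552	6.1293	4.763	6.5744	0.258	7.4882	5.691	3.1562	2.895	1.1961	-0.4471	4.795	3.8919	10.2154	4.4181	1.2617	1.9971	4.289	4.2843	5.1957	6.9931	8.5597	6.017	2.2626	4.0259	5.8948	-1.6931	3.0659	0.6849	1.041	1.3526	6.0219	6.2123	0.1283	1.4387	4.563	-3.3495	9.5151	4.5127	-1.7673	5.0911	0.3574	6.324	5.7343	-0.3862	-0.2513	0.2983	7.4653	-2.6861	1.8174	4.205	6.7593	3.2633	-0.2674	9.1138	6.1121	-4.165	3.1542	2.8875	6.9646	9.0613
AT	9.7196	3.5471	1.7943	3.0192	-1.8068	10.5766	2.401	7.969	-2.4618	7.8146	5.9701	2.4242	3.7696	2.4614	4.9975	4.174	7.953	5.9051	5.7553	3.1854	0.849	3.5016	5.2492	4.1724	8.2839	8.6413	5.6549	5.0407	10.767	3.6001	-0.5022	3.1709	0.9258	2.3387	-3.8047	7.3147	7.1418	-1.5055	0.348	7.3312	1.8686	8.8512	6.1888	-1.3537	4.1029	1.111	7.9929	5.4904	1.4268	-3.023	1.7249	5.8847	-2.2089	2.5146	3.5786	5.9978	4.8345	-2.3905	9.4797	6.2424	-2.2421	2.2117	3.7245	6.5534	8.8252
CA	5.7071	3.3021	2.8808	1.5661	-1.6996	8.0486	5.1074	1.0559	-3.5912	7.8714	9.0952	3.0826	3.6469	6.242	1.9759	1.4892	5.0061	5.1146	3.7935	2.1797	-0.3844	3.7897	5.5389	4.8498	5.8086	10.0257	7.2437	3.7347	6.0484	5.9464	6.5764	3.2623	-0.8701	2.2919	-2.4058	6.5274	6.8864	-1.2018	1.3083	3.9236	1.8196	7.2681	5.3983	0.9102	5.3973	1.0744	5.4986	2.9699	1.0242	1.1248	-3.6547	4.8653	-3.865	2.0488	3.7772	6.7299	7.5668	-4.1154	7.8103	6.6558	0.4731	1.1075	3.5365	6.0326	5.1115
CC	6.657	5.5258	0.6284	7.0013	-1.6894	6.0757	0.0438	6.8439	-1.7873	7.2231	6.5592	2.301	3.2507	3.4205	2.1267	3.5203	4.9583	6.7117	5.1134	1.1971	-0.8241	4.6075	5.0046	4.6468	9.2355	7.3107	7.7416	5.2877	8.0065	5.3016	4.7204	2.9547	1.6852	1.8776	-3.3127	6.3461	7.2905	-2.2114	-0.0544	3.8186	1.5077	8.579	6.4069	-1.5915	6.0088	1.0084	7.5338	3.301	1.1392	-1.4454	1.9954	7.0683	-2.5471	1.7125	2.2221	5.6906	8.5871	2.757	10.122	6.9492	-1.8411	-0.2382	2.6062	6.0267	11.4555
CG	5.8685	1.7339	3.0268	7.3263	-2.691	7.511	6.3543	7.7682	-1.3153	6.4968	7.9907	3.0556	3.6965	8.9846	2.1282	0.5234	6.8376	8.1701	4.7388	1.8119	2.3499	5.1458	3.9385	4.4163	3.0345	8.6006	6.5381	7.4304	7.1331	7.8952	3.2443	5.5098	3.1065	-0.4504	-3.297	5.9887	7.3326	-0.01	-0.4115	7.4358	-2.5196	7.0225	5.3152	0.5292	4.5108	1.3394	1.8942	2.6912	1.3538	3.1532	-2.9717	4.6477	-4.7447	2.3224	2.5529	6.9515	9.5477	-0.0748	9.8074	3.8082	-1.2862	3.1838	2.2884	4.7593	3.6011
CT	9.0314	4.6325	-0.2477	9.1478	-1.8067	7.8101	0.8822	11.7227	-1.8045	9.2521	7.8901	4.6854	3.7555	3.8643	0.9123	2.8877	6.1273	8.1595	4.8614	3.7619	0.9243	4.393	4.9571	5.4377	12.2152	8.6893	6.3879	0.6196	7.5017	6.1743	6.1987	4.3111	-1.7046	-0.3096	-1.9342	4.9816	7.2141	-1.1014	0.2986	6.2013	1.144	5.0905	6.259	-0.9615	6.0457	0.1386	7.5405	4.6771	0.4106	-1.4161	-0.4087	6.9718	-0.7998	1.8635	4.7419	9.4125	1.7855	1.1122	9.5234	9.1897	-0.2489	1.2225	4.0779	5.8462	7.7775
GA	6.8076	3.2277	-0.9304	3.021	-1.4977	9.0381	2.7565	7.6365	1.0128	7.3965	10.8538	3.9441	3.6149	5.3068	4.0724	4.9973	5.3711	8.5748	2.8406	0.2312	-1.6115	3.117	3.2565	3.7436	5.4867	8.872	6.6049	-1.441	5.5264	6.7735	1.8165	4.2624	0.8816	0.17	-4.4586	6.0155	6.8106	-0.5002	-2.2203	7.861	1.7735	6.4828	7.1893	-1.9606	4.1732	0.0463	7.395	4.8372	1.0998	-0.8872	0.2388	4.6445	-0.5343	2.2457	4.013	7.7213	3.9225	-3.7973	8.8425	7.5693	2.8911	3.9361	3.7111	6.6891	8.5285
GC	5.873	3.8489	-1.3733	4.9249	-2.3429	8.7659	4.1579	6.2104	0.6108	7.6658	7.8221	4.3829	3.4001	2.1337	1.3787	3.8616	7.0457	8.973	7.3952	2.5126	2.6781	3.7023	4.0253	4.3932	10.5186	8.0286	4.7994	-0.8327	5.8984	8.03	3.2665	3.2738	1.5926	2.4588	-0.2293	5.4833	6.3589	-0.7965	0.8559	8.3353	0.9325	10.4225	6.1251	-1.5188	5.1302	0.1587	7.5561	1.9774	1.1175	-0.1408	-0.9807	6.0996	-1.3076	2.3132	4.2855	8.5007	5.0092	-1.7772	8.8058	6.4599	1.9138	4.9595	2.0118	7.2703	2.4191
GG	0.2285	4.2241	-0.3886	6.1114	-2.0269	7.6306	1.9662	6.8939	0.8895	8.2646	6.8118	2.7167	4.5202	8.5368	3.0159	2.4221	5.4381	6.6626	6.1934	2.5692	-0.8173	4.2235	1.7587	4.8833	7.8936	9.3643	6.5206	-1.5138	8.9701	8.6385	1.5004	6.2953	0.3571	-1.4427	-0.9049	5.7563	7.6516	-1.649	1.4907	10.0736	0.9359	10.2406	5.3506	-4.3293	7.8014	-0.6487	3.2811	3.6062	1.2332	3.3877	-2.6315	6.9556	-4.3848	1.8664	3.606	9.1042	2.4319	-3.8897	6.0168	5.0324	0.9893	1.5249	1.8895	5.9105	9.1384
GT	5.5817	5.1967	-0.2548	5.3871	-2.0201	8.7597	5.5102	7.0447	-2.4326	7.8586	8.6209	4.9247	3.5006	4.6451	2.1583	1.7813	3.9486	5.7192	6.3171	3.9353	2.3697	3.5056	2.7621	5.1267	8.4294	10.5648	6.273	-1.7333	7.365	6.0283	3.9157	4.8132	-0.1682	-1.1629	-3.0439	5.3931	6.3331	-0.5837	-1.2657	4.1697	0.998	5.8829	7.9939	-1.8437	5.616	1.8054	2.8102	3.5083	1.1704	1.7319	-5.0255	5.927	-4.1675	2.2847	4.7545	9.0288	4.0394	1.306	7.5256	5.543	2.4533	3.5223	0.4872	6.5994	7.6461
TA	9.7783	3.871	1.869	4.1393	-2.4637	6.8667	1.4526	4.7981	-2.855	8.8522	8.4868	4.0163	4.6108	2.7759	4.4061	0.6588	10.6802	8.5662	7.8005	4.0379	-4.6674	3.8276	2.9889	5.3108	8.6239	8.4492	5.5989	-1.8869	6.9971	6.8835	2.0489	3.6305	0.8514	0.6025	2.1461	4.668	5.2755	-0.8889	-0.3979	10.3687	0.9911	7.9984	6.4655	-1.8614	5.6399	-0.1467	5.1893	1.9649	0.765	2.3662	-0.2533	6.6044	-2.7674	2.1344	4.9434	8.8938	3.7649	1.129	6.3874	5.8503	-1.2395	0.1026	1.4655	6.3403	3.7785
TC	5.1865	2.4991	-2.8503	8.5943	-1.7959	6.1838	6.2596	2.9232	0.159	6.3507	6.7604	4.4643	3.3738	-1.1746	4.1648	2.2628	8.1056	6.2609	7.7662	1.1708	-0.7326	4.4632	4.1428	4.441	4.017	7.6347	5.9467	0.7588	7.0667	6.8466	4.4777	3.9023	-0.4945	-0.4169	0.6906	4.9268	6.9221	-0.7986	-0.8682	10.3646	2.2168	12.0885	7.8994	-2.4829	6.6747	-0.2862	6.6299	2.1205	2.6283	2.3757	0.6504	6.0263	-1.9063	1.81	4.8569	4.453	8.9923	-1.7651	9.095	8.4753	-3.764	3.0305	1.7438	7.1836	5.5089
TG	5.6549	1.7498	-0.4382	4.5338	-1.3478	5.2306	7.4387	9.0449	-3.3611	5.5582	8.3871	4.058	4.2103	6.8484	7.4271	2.3944	7.3394	6.8801	6.1379	3.4681	-0.9423	6.0566	2.0789	4.0557	10.234	8.0148	4.4937	2.7861	9.0521	8.6564	6.8563	3.3721	0.3094	3.0367	0.5368	5.3146	6.7855	-2.1681	-2.0241	9.188	-0.8035	9.527	5.2063	-2.0309	4.7254	1.0219	5.7523	2.7403	0.6323	-0.3013	2.0719	6.017	0.8458	2.2604	2.2384	8.8757	10.0508	1.0615	10.2594	8.2346	-0.6648	2.9417	-0.3698	5.7326	5.7447
TT	3.2888	2.8555	-1.9091	3.9987	-1.171	5.3558	3.4261	6.6422	-4.0062	7.7015	8.8202	4.4885	2.9721	3.8543	6.0846	2.3222	7.9177	8.8391	3.6435	2.9377	-0.1176	3.9867	7.176	3.9796	8.1802	6.9141	5.0985	5.2223	9.8687	5.8612	6.5813	3.4748	-0.812	-1.0981	-2.6783	6.8475	6.7916	-1.2151	-0.6861	4.8418	-0.9285	4.8769	4.7258	0.0333	1.7625	2.2378	8.527	3.734	2.2934	3.4974	0.1939	4.2101	-3.3082	1.8723	1.5569	7.3769	7.9583	-3.4872	10.8792	4.8027	-3.0838	4.3189	4.4552	6.7707	9.0857
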