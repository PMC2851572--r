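te_id	family	chrom_arm	cytoband	te_class	pair_id	freq_north	freq_south	p_raw	fdr_printed	fdr_bold
FBti0018880	Bari1	2R	55F8	putatively_adaptive	AU2007	0.48	0.61	0.2017	0.4344	FALSE
FBti0018880	Bari1	2R	55F8	putatively_adaptive	AU2008	0.50	0.57	0.5262	0.6405	FALSE
FBti0018880	Bari1	2R	55F8	putatively_adaptive	NA	0.55	0.69	0.1767	0.2748	FALSE
FBti0019056	pogo	X	12F1	putatively_adaptive	AU2007	0.61	0.48	0.2000	0.5090	FALSE
FBti0019056	pogo	X	12F1	putatively_adaptive	AU2008	0.38	0.65	0.0098	0.0458	TRUE
FBti0019056	pogo	X	12F1	putatively_adaptive	NA	0.47	0.60	0.2757	0.3509	FALSE
FBti0019065	pogo	X	13C1	putatively_adaptive	AU2007	0.21	0.48	0.0108	0.0758	FALSE
FBti0019065	pogo	X	13C1	putatively_adaptive	AU2008	0.43	0.33	0.2823	0.4392	FALSE
FBti0019065	pogo	X	13C1	putatively_adaptive	NA	0.73	0.80	0.3870	0.4515	FALSE
FBti0019144	Rt1b	2L	31A3	putatively_adaptive	AU2007	0.18	0.44	0.0449	0.1573	FALSE
FBti0019144	Rt1b	2L	31A3	putatively_adaptive	AU2008	0.06	0.21	0.0676	0.1578	FALSE
FBti0019144	Rt1b	2L	31A3	putatively_adaptive	NA	0.17	0.44	0.0113	0.0395	TRUE
FBti0019164	X-element	2L	34A5	putatively_adaptive	AU2007	0.34	0.48	0.2011	0.4693	FALSE
FBti0019164	X-element	2L	34A5	putatively_adaptive	AU2008	0.35	0.80	6e-05	0.0008	TRUE
FBti0019164	X-element	2L	34A5	putatively_adaptive	NA	0.39	0.23	0.0911	0.1594	FALSE
FBti0019170	F-element	2L	34C4	putatively_adaptive	AU2007	0.18	0.45	0.0063	0.0885	FALSE
FBti0019170	F-element	2L	34C4	putatively_adaptive	AU2008	0.26	0.43	0.1240	0.2170	FALSE
FBti0019170	F-element	2L	34C4	putatively_adaptive	NA	0.25	0.24	0.9025	0.9025	FALSE
FBti0019372	S-element	3R	88A4	putatively_adaptive	AU2007	0.16	0.40	0.0103	0.0959	FALSE
FBti0019372	S-element	3R	88A4	putatively_adaptive	AU2008	0.04	0.26	0.0024	0.0168	TRUE
FBti0019372	S-element	3R	88A4	putatively_adaptive	NA	0.25	0.11	0.0770	0.1539	FALSE
FBti0019386	invader4	3R	89B7	putatively_adaptive	AU2007	0.23	0.43	0.0400	0.1867	FALSE
FBti0019386	invader4	3R	89B7	putatively_adaptive	AU2008	0.13	0.46	0.0004	0.0042	TRUE
FBti0019386	invader4	3R	89B7	putatively_adaptive	NA	0.50	0.20	0.0017	0.0080	TRUE
FBti0019430	Doc	3R	96D1	putatively_adaptive	AU2007	0.75	0.80	0.6107	0.7772	FALSE
FBti0019430	Doc	3R	96D1	putatively_adaptive	AU2008	0.73	0.91	0.0205	0.0819	FALSE
FBti0019430	Doc	3R	96D1	putatively_adaptive	NA	0.74	0.57	0.0881	0.1645	FALSE
FBti0019443	Rt1b	3R	98B3	putatively_adaptive	AU2007	0.11	0.45	0.0003	0.0077	TRUE
FBti0019443	Rt1b	3R	98B3	putatively_adaptive	AU2008	0.00	0.39	6e-08	1.7e-06	TRUE
FBti0019443	Rt1b	3R	98B3	putatively_adaptive	NA	0.14	0.11	0.6666	0.7179	FALSE
FBti0019624	hopper	X	10B2	putatively_adaptive	AU2007	0.55	0.43	0.2858	0.5001	FALSE
FBti0019624	hopper	X	10B2	putatively_adaptive	AU2008	0.26	0.48	0.0324	0.1134	FALSE
FBti0019624	hopper	X	10B2	putatively_adaptive	NA	0.45	0.48	0.8308	0.8615	FALSE
FBti0019627	pogo	X	10C6-7	putatively_adaptive	AU2007	0.57	0.64	0.5201	0.7665	FALSE
FBti0019627	pogo	X	10C6-7	putatively_adaptive	AU2008	0.63	0.61	0.8767	0.9092	FALSE
FBti0019627	pogo	X	10C6-7	putatively_adaptive	NA	0.83	0.57	0.0109	0.0435	TRUE
FBti0019679	1731	X	20A1	putatively_adaptive	AU2007	0.63	0.65	0.7840	0.8443	FALSE
FBti0019679	1731	X	20A1	putatively_adaptive	AU2008	0.38	0.44	0.5699	0.6649	FALSE
FBti0019679	1731	X	20A1	putatively_adaptive	NA	0.59	0.48	0.2826	0.3441	FALSE
FBti0019747	F-element	X	20E2	putatively_adaptive	AU2007	0.25	0.30	0.5559	0.7782	FALSE
FBti0019747	F-element	X	20E2	putatively_adaptive	AU2008	0.17	0.19	0.8406	0.9053	FALSE
FBti0019747	F-element	X	20E2	putatively_adaptive	NA	0.23	0.10	0.1083	0.1783	FALSE
FBti0020042	jockey	3L	64D3	putatively_adaptive	AU2007	0.11	0.20	0.2075	0.4150	FALSE
FBti0020042	jockey	3L	64D3	putatively_adaptive	AU2008	0.04	0.12	0.3256	0.4558	FALSE
FBti0020042	jockey	3L	64D3	putatively_adaptive	NA	0.25	0.15	0.2736	0.3648	FALSE
FBti0020046	Doc	3L	65A3	putatively_adaptive	AU2007	0.29	0.33	0.7339	0.8220	FALSE
FBti0020046	Doc	3L	65A3	putatively_adaptive	AU2008	0.15	0.27	0.1671	0.2752	FALSE
FBti0020046	Doc	3L	65A3	putatively_adaptive	NA	0.30	0.05	0.0016	0.0087	TRUE
FBti0020091	Rt1a	3L	68C1	putatively_adaptive	AU2007	0.63	0.83	0.0433	0.1732	FALSE
FBti0020091	Rt1a	3L	68C1	putatively_adaptive	AU2008	0.80	0.89	0.3165	0.4664	FALSE
FBti0020091	Rt1a	3L	68C1	putatively_adaptive	NA	0.83	0.65	0.0426	0.1086	FALSE
FBti0020119	S-element	3L	71E1	putatively_adaptive	AU2007	0.29	0.56	0.0203	0.1137	FALSE
FBti0020119	S-element	3L	71E1	putatively_adaptive	AU2008	0.40	0.75	0.0037	0.0206	TRUE
FBti0020119	S-element	3L	71E1	putatively_adaptive	NA	0.61	0.13	9.6e-07	1.3e-05	TRUE
FBti0018879	BS	2R	58E2	putatively_neutral	AU2007	0.61	0.67	0.6230	0.7585	FALSE
FBti0018879	BS	2R	58E2	putatively_neutral	AU2008	0.43	0.65	0.0356	0.1107	FALSE
FBti0018879	BS	2R	58E2	putatively_neutral	NA	0.60	0.34	0.0168	0.0523	FALSE
FBti0019079	BS	X	17A2	putatively_neutral	AU2007	0.18	0.14	0.5594	0.7459	FALSE
FBti0019079	BS	X	17A2	putatively_neutral	AU2008	0.08	0.13	0.4934	0.6579	FALSE
FBti0019079	BS	X	17A2	putatively_neutral	NA	0.20	0.52	0.0015	0.0108	TRUE
FBti0019133	BS	2L	28B2	putatively_neutral	AU2007	0.50	0.55	0.6584	0.7682	FALSE
FBti0019133	BS	2L	28B2	putatively_neutral	AU2008	0.59	0.79	0.0740	0.1594	FALSE
FBti0019133	BS	2L	28B2	putatively_neutral	NA	0.62	0.54	0.4579	0.5128	FALSE
FBti0019165	BS	2L	34B1	putatively_neutral	AU2007	0.41	0.52	0.2859	0.4708	FALSE
FBti0019165	BS	2L	34B1	putatively_neutral	AU2008	0.59	0.52	0.5196	0.6612	FALSE
FBti0019165	BS	2L	34B1	putatively_neutral	NA	0.43	0.66	0.0382	0.1069	FALSE
FBti0019604	BS	X	7E4	putatively_neutral	AU2007	0.43	0.43	0.9757	0.9757	FALSE
FBti0019604	BS	X	7E4	putatively_neutral	AU2008	0.43	0.43	0.9774	0.9774	FALSE
FBti0019604	BS	X	7E4	putatively_neutral	NA	0.50	0.72	0.0579	0.1246	FALSE
FBti0019771	1360	2L	36C6	putatively_neutral	AU2007	0.42	0.30	0.2563	0.4784	FALSE
FBti0019771	1360	2L	36C6	putatively_neutral	AU2008	0.33	0.50	0.0893	0.1787	FALSE
FBti0019771	1360	2L	36C6	putatively_neutral	NA	0.59	0.10	3.5e-07	9.7e-06	TRUE
FBti0020056	BS	3L	65D6	putatively_neutral	AU2007	0.18	0.05	0.0695	0.2163	FALSE
FBti0020056	BS	3L	65D6	putatively_neutral	AU2008	0.27	0.02	0.0364	0.1020	FALSE
FBti0020056	BS	3L	65D6	putatively_neutral	NA	0.07	0.21	0.0478	0.1116	FALSE
FBti0020057	BS	3L	65E4	putatively_neutral	AU2007	0.29	0.41	0.3054	0.4751	FALSE
FBti0020057	BS	3L	65E4	putatively_neutral	AU2008	0.58	0.75	0.0999	0.1865	FALSE
FBti0020057	BS	3L	65E4	putatively_neutral	NA	0.31	0.43	0.2398	0.3534	FALSE
FBti0020125	BS	3L	73A4	putatively_neutral	AU2007	0.11	0.11	0.9406	0.9754	FALSE
FBti0020125	BS	3L	73A4	putatively_neutral	AU2008	0.21	0.04	0.0560	0.1426	FALSE
FBti0020125	BS	3L	73A4	putatively_neutral	NA	0.18	0.00	0.0010	0.0095	TRUE
FBti0020155	1360	3L	75E1-2	putatively_neutral	AU2007	0.52	0.67	0.1357	0.3801	FALSE
FBti0020155	1360	3L	75E1-2	putatively_neutral	AU2008	0.61	0.59	0.8316	0.9314	FALSE
FBti0020155	1360	3L	75E1-2	putatively_neutral	NA	0.33	0.44	0.2658	0.3721	FALSE
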