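transcript	gene	exon	start	end
NM_000088.4	COL1A1	1	1	108
NM_000088.4	COL1A1	2	109	225
NM_000088.4	COL1A1	3	226	297
NM_000088.4	COL1A1	4	298	423
NM_000088.4	COL1A1	5	424	486
NM_000088.4	COL1A1	6	487	558
NM_000088.4	COL1A1	7	559	675
NM_000088.4	COL1A1	8	676	747
NM_000088.4	COL1A1	9	748	804
NM_000088.4	COL1A1	10	805	936
NM_000088.4	COL1A1	11	937	1008
NM_000088.4	COL1A1	12	1009	1134
NM_000088.4	COL1A1	13	1135	1197
NM_000088.4	COL1A1	14	1198	1269
NM_000088.4	COL1A1	15	1270	1386
NM_000088.4	COL1A1	16	1387	1458
NM_000088.4	COL1A1	17	1459	1530
NM_000088.4	COL1A1	18	1531	1647
NM_000088.4	COL1A1	19	1648	1719
NM_000088.4	COL1A1	20	1720	1845
NM_000088.4	COL1A1	21	1846	1908
NM_000088.4	COL1A1	22	1909	1980
NM_000088.4	COL1A1	23	1981	2091
NM_000088.4	COL1A1	24	2092	2154
NM_000088.4	COL1A1	25	2155	2217
NM_000088.4	COL1A1	26	2218	2325
NM_000088.4	COL1A1	27	2326	2388
NM_000088.4	COL1A1	28	2389	2505
NM_000088.4	COL1A1	29	2506	2559
NM_000088.4	COL1A1	30	2560	2622
NM_000088.4	COL1A1	31	2623	2730
NM_000088.4	COL1A1	32	2731	2793
NM_000088.4	COL1A1	33	2794	2856
NM_000088.4	COL1A1	34	2857	2964
NM_000088.4	COL1A1	35	2965	3027
NM_000088.4	COL1A1	36	3028	3144
NM_000088.4	COL1A1	37	3145	3198
NM_000088.4	COL1A1	38	3199	3261
NM_000088.4	COL1A1	39	3262	3369
NM_000088.4	COL1A1	40	3370	3432
NM_000088.4	COL1A1	41	3433	3495
NM_000088.4	COL1A1	42	3496	3603
NM_000088.4	COL1A1	43	3604	3666
NM_000088.4	COL1A1	44	3667	3783
NM_000088.4	COL1A1	45	3784	3837
NM_000088.4	COL1A1	46	3838	3900
NM_000088.4	COL1A1	47	3901	4008
NM_000088.4	COL1A1	48	4009	4071
NM_000088.4	COL1A1	49	4072	4134
NM_000088.4	COL1A1	50	4135	4242
NM_000088.4	COL1A1	51	4243	4395
NM_000089.4	COL1A2	1	1	99
NM_000089.4	COL1A2	2	100	207
NM_000089.4	COL1A2	3	208	270
NM_000089.4	COL1A2	4	271	387
NM_000089.4	COL1A2	5	388	441
NM_000089.4	COL1A2	6	442	504
NM_000089.4	COL1A2	7	505	612
NM_000089.4	COL1A2	8	613	675
NM_000089.4	COL1A2	9	676	792
NM_000089.4	COL1A2	10	793	846
NM_000089.4	COL1A2	11	847	909
NM_000089.4	COL1A2	12	910	1026
NM_000089.4	COL1A2	13	1027	1080
NM_000089.4	COL1A2	14	1081	1143
NM_000089.4	COL1A2	15	1144	1251
NM_000089.4	COL1A2	16	1252	1314
NM_000089.4	COL1A2	17	1315	1377
NM_000089.4	COL1A2	18	1378	1485
NM_000089.4	COL1A2	19	1486	1548
NM_000089.4	COL1A2	20	1549	1665
NM_000089.4	COL1A2	21	1666	1719
NM_000089.4	COL1A2	22	1720	1782
NM_000089.4	COL1A2	23	1783	1890
NM_000089.4	COL1A2	24	1891	1953
NM_000089.4	COL1A2	25	1954	2016
NM_000089.4	COL1A2	26	2017	2124
NM_000089.4	COL1A2	27	2125	2187
NM_000089.4	COL1A2	28	2188	2304
NM_000089.4	COL1A2	29	2305	2358
NM_000089.4	COL1A2	30	2359	2421
NM_000089.4	COL1A2	31	2422	2529
NM_000089.4	COL1A2	32	2530	2592
NM_000089.4	COL1A2	33	2593	2655
NM_000089.4	COL1A2	34	2656	2763
NM_000089.4	COL1A2	35	2764	2823
NM_000089.4	COL1A2	36	2824	2931
NM_000089.4	COL1A2	37	2932	2976
NM_000089.4	COL1A2	38	2977	3030
NM_000089.4	COL1A2	39	3031	3129
NM_000089.4	COL1A2	40	3130	3183
NM_000089.4	COL1A2	41	3184	3237
NM_000089.4	COL1A2	42	3238	3336
NM_000089.4	COL1A2	43	3337	3390
NM_000089.4	COL1A2	44	3391	3498
NM_000089.4	COL1A2	45	3499	3543
NM_000089.4	COL1A2	46	3544	3597
NM_000089.4	COL1A2	47	3598	3696
NM_000089.4	COL1A2	48	3697	3750
NM_000089.4	COL1A2	49	3751	3804
NM_000089.4	COL1A2	50	3805	3903
NM_000089.4	COL1A2	51	3904	3957
NM_000089.4	COL1A2	52	3958	4101
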