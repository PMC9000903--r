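feature	class	couple1_asd	couple1_ctrl	couple1_log2fc	couple1_fisher_p	couple2_asd	couple2_ctrl	couple2_log2fc	couple2_fisher_p
hsa-miR-10b-5p	miRNA	27.1	79.7	-1.52	0.0000029	0.0	29.7	-4.94	0.0000000020
hsa-mir-192	miRNA	33.2	94.1	-1.48	0.000000057	0.3	8.0	-2.77	0.0078
hsa-miR-22-3p	miRNA	11.3	28.7	-1.26	0.0064	0.0	7.2	-3.04	0.016
hsa-miR-192-5p	miRNA	90.8	185.4	-1.02	0.000000016	0.0	20.8	-4.45	0.00000095
hsa-miR-6760-5p	miRNA	7.9	0.9	2.22	0.039	11.4	0.0	3.63	0.00098
hsa-miR-6766	miRNA	23.6	1.8	3.14	0.00001	27.0	0.0	4.81	0.000000015
hsa-miR-6839	miRNA	7.9	0.0	3.15	0.0078	113.3	0.0	6.84	0
hsa-miR-3976	miRNA	14.8	0.0	3.99	0.000061	36.1	14.4	1.27	0.0026
hsa-piR-28021	piRNA	0.0	429.1	-8.75	0	0.3	57.7	-5.47	0
hsa-piR-8876	piRNA	0.0	46.6	-5.57	0	0.0	9.6	-3.41	0.002
hsa-piR-12132	piRNA	0.0	43.9	-5.49	0	14.3	804.0	-5.72	0
hsa-piR-32989	piRNA	0.0	9.9	-3.44	0.002	2.3	37.7	-3.56	0.000000001
hsa-piR-5819	piRNA	0.0	7.2	-3.03	0.016	0.7	8.8	-2.57	0.021
hsa-piR-14261	piRNA	612.0	3592.7	-2.55	0	9.1	20.8	-1.11	0.043
hsa-piR-33186	piRNA	4681.1	23105.1	-2.30	0	0.0	5260.6	-12.36	0
hsa-piR-33033	piRNA	6091.9	20508.4	-1.75	0	2.9	1094.1	-8.12	0
hsa-piR-5751	piRNA	291.6	907.4	-1.63	0	0.0	32.1	-5.05	0
hsa-piR-8213	piRNA	11.3	28.7	-1.26	0.0064	1.0	8.0	-2.19	0.039
hsa-piR-32837	piRNA	413.8	944.1	-1.19	0	1.6	74.5	-4.85	0
hsa-piR-32914	piRNA	413.8	944.1	-1.19	0	1.6	74.5	-4.85	0
hsa-piR-28066	piRNA	1331.4	2873.5	-1.11	0	1.0	40.9	-4.41	0
hsa-piR-31090	piRNA	39.3	18.8	1.02	0.012	38.4	16.8	1.14	0.0064
hsa-piR-32953	piRNA	534.3	253.5	1.07	0	588.9	8.0	6.03	0
hsa-piR-26659	piRNA	267.1	121.8	1.13	0	608.1	283.0	1.10	0
hsa-piR-21363	piRNA	433.9	137.0	1.66	0	2058.3	484.9	2.08	0
hsa-piR-31508	piRNA	18.3	4.5	1.82	0.0043	35.2	2.4	3.41	0.00000001
hsa-piR-16407	piRNA	14.0	1.8	2.42	0.0042	230.8	10.4	4.34	0
hsa-piR-2750	piRNA	280.2	45.7	2.59	0	121.4	16.8	2.78	0
hsa-piR-30491	piRNA	68.1	8.1	2.93	0	157.9	55.3	1.50	0
hsa-piR-22093	piRNA	7.0	0.0	3.00	0.016	24.7	3.2	2.61	0.000027
hsa-piR-18568	piRNA	7.0	0.0	3.00	0.016	13.0	0.8	2.96	0.0018
hsa-piR-21890	piRNA	7.9	0.0	3.15	0.0078	27.0	4.0	2.48	0.000034
hsa-piR-13475	piRNA	18.3	0.9	3.35	0.000076	39.4	12.0	1.63	0.0002
hsa-piR-8932	piRNA	66.3	5.4	3.40	0	86.6	40.1	1.09	0.000037
hsa-piR-26586	piRNA	9.6	0.0	3.41	0.002	10.1	0.0	3.47	0.002
hsa-piR-12718	piRNA	9.6	0.0	3.41	0.002	232.1	46.5	2.30	0
hsa-piR-33000	piRNA	9.6	0.0	3.41	0.002	560.5	68.1	3.02	0
hsa-piR-30677	piRNA	11.3	0.0	3.63	0.00098	75.2	6.4	3.36	0
hsa-piR-33037	piRNA	14.8	0.0	3.99	0.000061	16.6	4.0	1.81	0.0072
hsa-piR-24148	piRNA	18.3	0.0	4.27	0.0000076	44.3	0.0	5.50	0
hsa-piR-3308	piRNA	18.3	0.0	4.27	0.0000076	21.2	4.0	2.15	0.00091
hsa-piR-2934	piRNA	73.3	2.7	4.33	0	197.9	56.1	1.80	0
hsa-piR-33019	piRNA	20.1	0.0	4.40	0.0000019	392.3	0.0	8.62	0
hsa-piR-3864	piRNA	60.2	1.8	4.46	0	99.3	4.0	4.32	0
hsa-piR-25822	piRNA	22.7	0.0	4.57	0.00000024	108.7	28.1	1.92	0
hsa-piR-11291	piRNA	46.3	0.9	4.64	0	123.0	45.7	1.41	0.000000003
hsa-piR-4194	piRNA	48.9	0.9	4.72	0	59.9	24.8	1.24	0.00019
hsa-piR-9502	piRNA	26.2	0.0	4.77	0.00000003	22.5	0.0	4.55	0.00000048
hsa-piR-8096	piRNA	27.9	0.0	4.86	0.000000007	83.0	11.2	2.78	0
hsa-piR-30323	piRNA	634.7	19.7	4.94	0	595.1	8.0	6.05	0
hsa-piR-32334	piRNA	34.0	0.0	5.13	0	15.6	0.0	4.06	0.000031
hsa-piR-892	piRNA	151.9	0.0	7.26	0	18.6	3.2	2.22	0.00085
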