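metric	Tx001	Tx002	Tx003	Tx004	Tx005	Tx006	Tx007	Tx008	Tx009	Tx010	Tx011	Tx012	Tx013
sequences	802	1439	571	160	837	723	1365	1225	802	1112	826	630	927
otus	743	1292	518	152	775	685	1144	1187	750	1011	785	623	868
shannon	5.24	5.15	5.01	5.61	5.33	4.79	5.87	2.10	5.66	4.72	5.31	2.87	5.60
gini_simpson	0.95	0.94	0.94	0.97	0.94	0.91	0.97	0.49	0.97	0.91	0.94	0.70	0.96
simpson_evenness	0.33	0.27	0.28	0.48	0.25	0.20	0.48	0.07	0.45	0.20	0.25	0.14	0.39
reciprocal_simpson	21.26	17.42	16.70	33.03	17.11	11.47	39.03	1.95	32.15	11.37	17.55	3.29	28.54
chao1	211.9	159.1	113.1	147.8	132.1	105.5	259.6	56.6	162.1	180.0	299.7	30.0	162.4
goods_coverage	0.67	0.67	0.73	0.68	0.68	0.74	0.55	0.87	0.66	0.70	0.62	0.94	0.63
faith_pd	2.89	2.83	2.61	3.39	3.24	3.21	3.82	1.79	3.27	2.20	3.63	1.58	3.15
ace	239.55	218.11	165.55	175.18	164.38	145.56	355.46	86.20	182.63	216.98	257.60	31.56	228.47
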