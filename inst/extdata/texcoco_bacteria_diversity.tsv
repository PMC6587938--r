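metric	Tx001	Tx002	Tx003	Tx004	Tx006	Tx007	Tx008	Tx009	Tx010	Tx011	Tx012	Tx013
sequences	668	676	436	323	231	794	304	700	297	245	280	167
otus	511	558	346	309	217	706	266	641	278	220	232	155
shannon	5.52	5.92	5.96	6.12	5.74	6.21	5.72	6.11	5.52	5.75	5.57	6.13
gini_simpson	0.96	0.98	0.97	0.98	0.98	0.98	0.97	0.98	0.97	0.98	0.97	0.98
simpson_evenness	0.40	0.54	0.48	0.66	0.64	0.71	0.58	0.71	0.47	0.61	0.60	0.78
reciprocal_simpson	27.08	42.34	38.77	54.82	42.81	61.27	39.16	57.23	29.99	41.67	35.11	61.27
chao1	323.00	349.14	207.43	178.06	130.08	197.24	93.25	168.35	132.33	129.50	70.00	126.00
goods_coverage	0.59	0.50	0.52	0.53	0.67	0.50	0.71	0.56	0.67	0.66	0.82	0.62
faith_pd	6.36	6.15	5.88	6.24	4.97	7.11	6.10	7.37	5.16	4.95	5.40	6.86
ace	222	337	223	227	133	224	128	182	138	144	74	131
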