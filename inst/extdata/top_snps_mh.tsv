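snp	chr	pos_bp	gene	mh_p	cc_p	dtdt_p	maf
rs12116935	1	36562133	FAM176B	6.98e-06	6.56e-04	1.04e-03	0.38
rs11583322	1	36594899	STK40	1.10e-08	7.39e-06	1.04e-04	0.38
rs1932933	1	160384670	NOS1AP	5.82e-06	1.99e-04	4.24e-03	0.37
rs10801629	1	196110990	NA	4.13e-06	1.18e-04	9.62e-03	0.40
rs10922323	1	196128944	NA	6.46e-06	1.52e-04	1.23e-02	0.40
rs1850344	3	108667763	NA	8.16e-06	1.33e-04	2.08e-02	0.38
rs4384980	3	183941763	NA	5.78e-07	9.17e-05	6.93e-04	0.42
rs2857839	4	3006428	GRK4	6.60e-06	1.11e-03	5.56e-04	0.39
rs1801058	4	3008948	GRK4	6.48e-06	9.67e-04	6.57e-04	0.39
rs2798303	4	3010385	GRK4	1.28e-06	2.17e-04	8.55e-04	0.42
rs994029	9	88565134	NA	1.98e-07	3.62e-04	1.18e-05	0.37
rs2398236	10	5321159	NA	9.07e-06	7.15e-04	1.96e-03	0.40
rs9423593	10	5322349	NA	8.32e-06	1.04e-03	5.20e-04	0.37
rs7076488	10	5323008	NA	2.13e-06	2.03e-04	1.49e-03	0.41
rs3781458	10	126333921	FAM53B	4.27e-06	2.70e-03	1.31e-05	0.37
rs3781452	10	126345119	FAM53B	6.86e-06	3.43e-03	1.81e-05	0.37
rs1503452	11	16408708	SOX6	3.21e-06	2.58e-04	1.80e-03	0.37
rs3924047	11	70507506	SHANK2	8.77e-06	2.19e-04	1.04e-02	0.44
rs4356270	12	90843346	NA	8.42e-06	8.12e-06	1.91e-01	0.35
rs12427267	12	90848103	NA	6.00e-07	6.04e-05	1.90e-03	0.38
rs11106345	12	90850631	NA	7.22e-06	8.83e-06	1.81e-01	0.35
rs10848190	12	129767988	NA	5.43e-06	4.83e-04	2.36e-03	0.39
rs1035717	14	69648452	SLC8A3	6.36e-06	1.32e-03	2.19e-04	0.41
rs4903712	14	77685346	NA	1.67e-06	3.40e-05	1.79e-02	0.27
rs17754467	14	77692276	NA	5.54e-07	3.20e-06	4.50e-02	0.23
rs1568447	17	70348607	NA	4.08e-06	5.26e-04	1.13e-03	0.38
rs9901283	17	70349427	GRIN2C	9.31e-06	8.18e-04	1.67e-03	0.38
rs11652088	17	70351427	GRIN2C	3.50e-06	4.58e-04	1.00e-03	0.38
rs8111589	19	50726398	OPA3	8.27e-06	7.50e-05	4.03e-02	0.44
rs2830045	21	26380280	APP	6.31e-06	1.77e-03	2.22e-04	0.37
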