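lncrna_id	regulation	mean_tpm_case	mean_tpm_control	log2fc	p_value	q_value
ENSMUST00000144016	up	100.2933	37.1633	1.43	7.69e-6	1.30e-3
ENSMUST00000141374	up	11.2500	4.4133	1.35	3.44e-5	4.47e-3
ENSMUST00000028291	up	5.9100	0.2167	4.77	1.06e-9	4.41e-7
ENSMUST00000154192	up	8.7400	1.7967	2.28	1.88e-10	8.49e-8
ENSMUST00000160679	up	6.0767	1.8800	1.69	4.36e-8	1.27e-5
ENSMUST00000153923	up	8.1333	2.9133	1.48	5.19e-5	6.30e-3
ENSMUST00000218620	up	16.3267	0.7067	4.53	2.36e-5	3.26e-3
ENSMUST00000211218	up	13.5300	5.7400	1.24	2.18e-6	4.44e-4
ENSMUST00000180635	up	10.6967	4.5000	1.25	2.93e-7	7.31e-5
ENSMUST00000150127	up	9.7400	0.4167	4.55	8.10e-44	1.21e-39
ENSMUST00000127786	up	124.8767	0.0867	10.49	5.72e-11	2.86e-8
ENSMUST00000152985	up	6.0333	0.0067	9.82	1.07e-5	1.72e-3
ENSMUST00000145174	up	19.7200	1.2567	3.97	6.20e-5	7.31e-3
ENSMUST00000132577	up	6.4433	2.6667	1.27	2.52e-5	3.45e-3
ENSMUST00000197854	up	27.5900	13.1100	1.07	2.18e-5	3.08e-3
MSTRG.11359.1	up	11.7967	0.0300	8.62	3.67e-9	1.36e-6
MSTRG.17500.2	up	5.7800	0.0001	15.82	1.77e-26	7.06e-23
MSTRG.16327.2	up	7.6200	0.0001	16.22	1.56e-5	2.36e-3
MSTRG.6530.1	up	19.1900	0.1800	6.74	8.09e-5	9.10e-3
MSTRG.6775.12	up	10.2333	0.0001	16.64	7.89e-16	8.71e-13
MSTRG.10674.1	up	5.3633	0.0001	15.71	6.04e-24	1.80e-20
MSTRG.17055.1	up	5.4067	0.0001	15.72	1.75e-12	1.14e-9
MSTRG.14838.1	up	13.2767	0.0767	7.44	1.23e-7	3.31e-5
MSTRG.1243.32	up	8.8267	0.0001	16.43	4.48e-23	1.22e-19
ENSMUST00000125930	down	5.2800	14.2633	-1.43	2.43e-5	3.35e-3
ENSMUST00000182575	down	0.0001	20.5667	-17.65	1.47e-26	6.25e-23
ENSMUST00000119305	down	2.1933	19.1767	-3.13	2.26e-5	3.18e-3
ENSMUST00000218432	down	11.9700	31.6733	-1.40	3.01e-12	1.85e-9
ENSMUST00000138202	down	0.2633	5.7567	-4.45	1.06e-15	1.13e-12
ENSMUST00000182642	down	2.0900	10.1333	-2.28	2.83e-7	7.14e-5
ENSMUST00000162088	down	0.0001	10.6933	-16.71	2.94e-13	2.12e-10
ENSMUST00000184170	down	2.6967	8.6433	-1.68	1.49e-5	2.26e-3
ENSMUST00000203561	down	2.6567	7.0467	-1.41	8.76e-6	1.45e-3
ENSMUST00000126582	down	1.2467	8.1333	-2.71	4.24e-9	1.55e-6
ENSMUST00000126344	down	2.8900	6.1167	-1.08	3.37e-5	4.40e-3
ENSMUST00000168634	down	5.0733	14.7667	-1.54	3.31e-5	4.34e-3
ENSMUST00000151020	down	0.4867	5.4433	-3.48	1.13e-8	3.83e-6
ENSMUST00000134954	down	2.4700	7.9333	-1.68	6.42e-5	7.52e-3
ENSMUST00000218286	down	1.0900	6.7000	-2.62	1.75e-5	2.60e-3
ENSMUST00000197200	down	3.1900	7.1833	-1.17	3.42e-5	4.45e-3
ENSMUST00000185523	down	3.6467	7.9267	-1.12	1.16e-6	2.63e-4
ENSMUST00000131037	down	1.3800	48.6333	-5.14	2.01e-20	4.30e-17
ENSMUST00000173081	down	0.2433	6.9100	-4.83	4.30e-14	3.52e-11
ENSMUST00000199803	down	0.1133	5.4200	-5.58	7.35e-6	1.25e-3
ENSMUST00000220428	down	10.6567	30.2200	-1.50	2.87e-5	3.85e-3
MSTRG.2483.2	down	0.2633	8.2800	-4.97	2.44e-6	4.84e-4
MSTRG.16159.9	down	2.2767	26.3967	-3.54	7.92e-10	3.31e-7
MSTRG.17585.1	down	0.0833	6.0233	-6.18	7.85e-6	1.32e-3
MSTRG.9309.1	down	0.0001	8.9167	-16.44	2.67e-14	2.35e-11
MSTRG.15980.1	down	3.5233	9.9133	-1.49	8.01e-9	2.80e-6
MSTRG.18159.11	down	0.2600	5.8400	-4.49	2.94e-7	7.31e-5
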