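lncrna_id	regulation	mean_tpm_case	mean_tpm_control	log2fc	p_value	q_value
ENSMUST00000141677	up	19.5700	6.9000	1.50	2.55e-5	3.46e-3
ENSMUST00000131052	up	5.2167	0.2933	4.15	7.73e-8	2.58e-5
ENSMUST00000189564	up	7.1500	1.5533	2.20	8.06e-5	8.92e-3
ENSMUST00000155277	up	9.8033	4.9000	1.00	3.88e-5	4.94e-3
ENSMUST00000123670	up	6.5933	1.7300	1.93	9.33e-6	1.49e-3
ENSMUST00000150644	up	5.6833	0.0167	8.41	1.18e-5	1.81e-3
ENSMUST00000156420	up	9.3233	0.3333	4.81	7.75e-8	2.58e-5
ENSMUST00000221971	up	17.5367	8.4833	1.05	4.92e-9	2.02e-6
ENSMUST00000205311	up	7.7400	2.6833	1.53	2.00e-5	2.83e-3
ENSMUST00000126335	up	8.0900	3.2067	1.34	1.91e-7	5.62e-5
ENSMUST00000127786	up	131.1167	0.0467	11.46	3.74e-9	1.57e-6
ENSMUST00000182231	up	5.6033	0.0001	15.77	1.17e-5	1.80e-3
ENSMUST00000111019	up	11.4500	1.9933	2.52	1.42e-6	3.14e-4
ENSMUST00000160318	up	12.4067	1.5533	3.00	4.29e-7	1.10e-4
ENSMUST00000148373	up	9.0667	2.2800	1.99	5.25e-6	9.48e-4
ENSMUST00000205779	up	11.2933	3.9233	1.53	1.03e-15	1.08e-12
ENSMUST00000145025	up	12.8433	1.2333	3.38	6.51e-19	9.91e-16
MSTRG.10455.14	up	17.0067	7.5200	1.18	1.62e-5	2.38e-3
MSTRG.11359.1	up	6.9667	0.0001	16.09	2.38e-9	1.04e-6
MSTRG.15393.1	up	6.9567	0.0001	16.09	9.26e-18	1.19e-14
MSTRG.17500.2	up	8.6633	0.0001	16.40	1.44e-29	5.35e-26
MSTRG.12843.10	up	7.8933	0.0001	16.27	4.89e-5	5.94e-3
MSTRG.16327.2	up	8.7600	0.0001	16.42	3.75e-6	7.06e-4
MSTRG.3640.2	up	8.8033	0.0001	16.43	5.55e-28	1.88e-24
MSTRG.3877.7	up	8.7900	0.5433	4.02	1.72e-9	7.76e-7
MSTRG.14838.1	up	14.0300	0.0001	17.10	1.45e-9	6.67e-7
MSTRG.1243.32	up	10.1600	0.0001	16.63	6.51e-23	1.43e-19
MSTRG.5009.1	up	7.7933	0.0001	16.25	2.35e-9	1.03e-6
ENSMUST00000145774	down	0.6400	5.8500	-3.19	1.41e-5	2.11e-3
ENSMUST00000132392	down	8.0467	23.1867	-1.53	1.13e-8	4.37e-6
ENSMUST00000182451	down	3.9300	12.9333	-1.72	2.04e-5	2.87e-3
ENSMUST00000161415	down	1.6833	9.1633	-2.44	1.14e-8	4.37e-6
ENSMUST00000161637	down	0.4733	19.3467	-5.35	1.72e-7	5.24e-5
ENSMUST00000124691	down	0.3933	6.9067	-4.13	1.45e-5	2.15e-3
ENSMUST00000141539	down	3.9967	12.0300	-1.59	2.02e-7	5.84e-5
ENSMUST00000162401	down	1.7367	6.2900	-1.86	2.21e-10	1.14e-7
ENSMUST00000139277	down	31.3367	121.4033	-1.95	4.41e-5	5.46e-3
ENSMUST00000129857	down	1.1600	21.8867	-4.24	2.39e-7	6.65e-5
ENSMUST00000184170	down	0.0001	9.6800	-16.56	6.00e-12	3.79e-9
ENSMUST00000209301	down	4.8000	10.6767	-1.15	1.75e-6	3.74e-4
ENSMUST00000199237	down	0.1767	8.6533	-5.61	3.10e-6	5.98e-4
ENSMUST00000137980	down	8.0300	18.9333	-1.24	1.63e-6	3.51e-4
ENSMUST00000141357	down	2.9133	8.0067	-1.46	9.04e-5	9.80e-3
ENSMUST00000210394	down	1.2167	13.6133	-3.48	1.68e-6	3.61e-4
ENSMUST00000146588	down	0.9167	9.7400	-3.41	4.69e-9	1.93e-6
ENSMUST00000144628	down	4.8300	30.4733	-2.66	1.13e-5	1.76e-3
ENSMUST00000145741	down	0.5200	16.0600	-4.95	7.81e-6	1.29e-3
ENSMUST00000221246	down	0.3400	5.2700	-3.95	7.80e-5	8.68e-3
MSTRG.17500.1	down	0.6133	8.8667	-3.85	1.23e-43	7.04e-40
MSTRG.18699.11	down	0.0001	8.9733	-16.45	2.11e-22	4.50e-19
MSTRG.7748.1	down	0.0001	12.9100	-16.98	7.52e-26	2.08e-22
MSTRG.18699.5	down	7.7767	32.3900	-2.06	1.40e-5	2.09e-3
MSTRG.8598.3	down	0.0001	116.1733	-20.15	1.39e-31	5.44e-28
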