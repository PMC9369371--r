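lncrna_id	log2fc_cortex	p_cortex	q_cortex	regulation_cortex	log2fc_hippocampus	p_hippocampus	q_hippocampus	regulation_hippocampus
ENSMUST00000127786	11.46	3.74e-9	1.57e-6	up	10.49	5.72e-11	2.86e-8	up
ENSMUSG00000098912	-16.56	6.00e-12	3.79e-9	down	-1.68	1.49e-5	2.26e-3	down
MSTRG.11359.1	16.09	2.38e-9	1.04e-6	up	8.62	3.67e-9	1.36e-6	up
MSTRG.17500.2	16.40	1.44e-29	5.35e-26	up	15.82	1.77e-26	7.06e-23	up
MSTRG.16327.2	16.42	3.75e-6	7.06e-4	up	16.22	1.56e-5	2.36e-3	up
MSTRG.14838.1	17.10	1.45e-9	6.67e-7	up	7.44	1.23e-7	3.31e-5	up
MSTRG.1243.32	16.63	6.51e-23	1.43e-19	up	16.43	4.48e-23	1.22e-19	up
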