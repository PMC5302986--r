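mirna	TamR1	TamR4	TamR8
miR-101*	-1.02	-3.05	-1.37
miR-1201	-0.94	-1.36	-1.27
miR-1248	-1.68	-1.61	-1.01
miR-652	-1.99	-1.17	-1.64
miR-95	-1.82	-2.45	-1.19
miR-135b	-1.89	-2.16	-2.33
miR-196a	-1.54	-0.71	-1.65
miR-135a	-2.84	-6.16	-4.74
miR-130b	0.75	0.94	0.89
miR-130b*	1.06	1.55	0.88
miR-152	1.29	1.4	1.49
miR-181b	0.89	1.14	0.95
miR-203	2.2	1.34	1.12
miR-210	0.7	1.18	1.49
miR-22*	0.97	0.88	0.82
miR-339-5p	1	1.26	0.8
miR-516a-5p	3.47	2.87	2.46
miR-517c	2.06	1.66	1.06
miR-519a	2.23	1.69	1.2
miR-519e	1.98	1.15	0.97
miR-551b	2.09	5.79	3.51
miR-582-5p	2.43	0.86	1.93
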