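class	size	centrosome	cytoplasm	actin_filaments	intermediate_filaments	microtubules	er	golgi	mitochondria	nucleoli	nucleus	nucleus_wo_nucleoli	plasma_membrane	vesicles
centrosome	16	0.38	0.06	0	0	0	0	0.19	0	0	0.13	0	0	0.25
cytoplasm	129	0	0.9	0	0	0.01	0	0.01	0.03	0	0	0	0	0.05
actin_filaments	10	0	0.6	0	0.1	0	0	0	0.1	0	0	0	0.1	0.1
intermediate_filaments	9	0	0.33	0	0.33	0.11	0	0	0.22	0	0	0	0	0
microtubules	21	0	0.29	0	0	0.67	0.05	0	0	0	0	0	0	0
er	41	0	0.2	0	0	0	0.68	0	0.1	0	0.02	0	0	0
golgi	64	0	0.02	0	0	0	0	0.86	0.08	0	0	0	0	0.05
mitochondria	148	0	0	0	0.01	0	0	0.01	0.96	0	0	0	0	0.02
nucleoli	67	0	0	0	0	0	0	0	0	0.87	0.06	0.04	0	0.03
nucleus	110	0	0.01	0	0	0	0	0	0	0.05	0.36	0.58	0	0
nucleus_wo_nucleoli	255	0	0	0	0	0	0	0	0	0.02	0.11	0.87	0	0
plasma_membrane	17	0	0.59	0	0	0	0	0	0.06	0	0.06	0	0.18	0.12
vesicles	71	0.01	0.04	0	0	0	0.01	0.04	0.04	0	0.01	0	0	0.83
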