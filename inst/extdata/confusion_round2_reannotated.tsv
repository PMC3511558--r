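class	size	centrosome	cytoplasm	actin_filaments	intermediate_filaments	microtubules	er	golgi	mitochondria	nucleoli	nucleus	nucleus_wo_nucleoli	plasma_membrane	vesicles
centrosome	16	0.31	0.06	0	0	0	0	0.19	0.13	0.06	0.06	0	0	0.19
cytoplasm	126	0	0.94	0	0	0	0	0	0.02	0	0	0	0	0.04
actin_filaments	10	0	0.40	0.10	0.10	0	0	0	0.10	0	0	0	0.20	0.10
intermediate_filaments	12	0	0.25	0	0.42	0	0.08	0	0.25	0	0	0	0	0
microtubules	18	0	0.17	0	0	0.78	0.06	0	0	0	0	0	0	0
er	40	0	0.13	0	0	0	0.78	0	0.10	0	0	0	0	0
golgi	64	0	0.02	0	0	0	0	0.97	0	0	0	0	0	0.02
mitochondria	148	0	0.01	0	0.01	0	0.01	0.01	0.95	0	0	0.01	0	0.01
nucleoli	66	0	0.02	0	0	0	0	0	0	0.88	0.05	0.03	0	0.03
nucleus	91	0	0	0	0	0	0	0	0	0.07	0.30	0.64	0	0
nucleus_wo_nucleoli	272	0	0	0	0	0	0	0	0	0.01	0.04	0.94	0	0
plasma_membrane	14	0	0.50	0	0	0	0	0	0.07	0	0.07	0	0.29	0.07
vesicles	73	0	0.05	0	0	0	0	0.01	0.07	0	0.03	0.01	0	0.82
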