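class	size	centrosome	cytoplasm	cytoskeleton	er	golgi	lys_pero_endo	mitochondria	nucleoli	nucleus	nucleus_wo_nucleoli	plasma_membrane
centrosome	12	0.42	0.08	0	0	0.33	0	0.08	0	0	0.08	0
cytoplasm	326	0	0.97	0.01	0	0	0	0.02	0	0	0.01	0
cytoskeleton	37	0	0.51	0.46	0	0	0	0.03	0	0	0	0
er	34	0	0.18	0	0.76	0	0	0.06	0	0	0	0
golgi	41	0	0.02	0	0	0.9	0	0.05	0	0	0.02	0
lys_pero_endo	26	0	0.15	0	0	0.04	0.62	0.15	0	0.04	0	0
mitochondria	104	0.01	0.13	0	0	0.01	0	0.86	0	0	0	0
nucleoli	37	0	0	0	0	0	0	0	0.92	0	0.08	0
nucleus	87	0	0	0	0	0	0.02	0	0.06	0.34	0.57	0
nucleus_wo_nucleoli	167	0	0	0	0	0	0	0	0.01	0.08	0.92	0
plasma_membrane	7	0	0.86	0	0	0	0	0.14	0	0	0	0
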