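category	svm	random_svm	cluster	random_cluster
am_right	14	2	14	2
partially_right	3	6	0	3
both_right	0	48	0	29
am_wrong	37	23	43	42
both_wrong	2	1	5	4
negative	2	0	1	0
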