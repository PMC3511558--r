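category	svm	random_svm	cluster	random_cluster
am_right	21	4	2	4
partially_right	7	5	0	1
both_right	0	17	0	33
am_wrong	60	34	8	18
both_wrong	9	4	1	8
negative	2	1	1	1
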