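1.018	3.411	1	0
3.411	5.827	1	0
5.827	8.339	1	1
8.339	10.923	1	0
10.923	13.292	0	1
13.292	16.018	1	0
16.018	18.482	1	0
18.482	19.542	1	0
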