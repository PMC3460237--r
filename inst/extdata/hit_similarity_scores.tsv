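compound	pki	ecfp4_best_known
4	6.4	0.25
5	5.8	0.30
16	5.2	0.23
18	5.1	0.19
19	5.2	0.25
20	5.3	0.25
22	5.4	0.22
29	6.7	0.44
32	5.7	0.33
37	5.6	0.13
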