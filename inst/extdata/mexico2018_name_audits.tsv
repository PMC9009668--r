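commercial_name	verbal_sample_number	correctly_labeled	mislabeling_frequency	mislabeling_diversity	substitutability_frequency	substitutability_diversity
atun	58	52	6	4	15	4
salmon	39	37	2	2	3	2
cazon	32	29	3	3	5	3
dorado	31	19	12	9	11	10
marlin	18	1	17	5	0	0
tilapia	18	16	2	1	6	6
mero	15	2	13	9	2	2
robalo	15	7	8	8	3	3
mojarra	15	9	6	3	1	1
huachinango	13	6	7	7	1	1
basa	12	12	0	0	8	3
pargo	11	7	4	4	2	1
sierra	9	1	8	7	3	3
curvina	6	3	3	3	3	2
cochito	6	4	2	2	3	2
lenguado	6	4	2	2	0	0
peto	6	4	2	2	5	3
trucha	6	4	2	2	0	0
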