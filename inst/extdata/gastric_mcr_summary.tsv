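#Published minimal common regions of recurrent (>=25%) copy-number alterations
#in a 20-sample gastric cancer cohort (13 primary tumour tissues, 7 cell lines).
#Carrier counts per class and region boundaries in Mb, as printed in the study report.
alteration	direction	tissues	cell_lines	start_mb	end_mb
1q41-q43.1	gain	2	3	216.31	233.61
5p13.3-q11.1	gain	1	4	30.18	49.60
7q21.3-q22.1	gain	4	3	97.33	101.93
8q24.13-q24.3	gain	3	2	126.45	146.25
8q24.3	gain	6	3	143.59	145.82
14q11.2	gain	0	5	22.89	23.94
17q12-q21.1	gain	3	3	35.02	35.30
17q22-q24.2	gain	2	3	50.45	64.10
19q12-qter	gain	4	3	33.89	63.25
20p13-qter	gain	5	3	0.04	57.98
9p24.3-p21.1	loss	3	4	1.05	28.86
18q12.3-q22.2	loss	3	5	39.48	65.59
18q22.3-qter	loss	2	5	70.95	74.65
21q11.2-q21.1	loss	3	3	14.37	19.44
Xq28	loss	4	1	152.24	153.45
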