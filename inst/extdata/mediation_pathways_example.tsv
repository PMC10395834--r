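exposure	mediator	outcome	b1	b2	b3	b	p	proportion
Alcohol drinker status: Current	Eubacterium ventriosum	CC	11.03	-19.24	-0.25	4.75	0.00	43.04
Bread intake	Bacteroides ovatus	BCR	0.54	0.63	0.11	0.07	0.04	12.64
Cereal type: Biscuit cereal	Erysipelotrichaceae	CRC	-2.99	2.44	-0.17	-0.42	0.94	13.97
Ferritin	Streptococcus thermophilus	CRC	0.27	-0.42	-0.22	0.09	0.02	34.22
Ferritin	Sutterellaceae unclassified	BR	0.35	0.72	-0.24	-0.18	0.97	-49.67
Lamb/mutton intake	Eubacterium siraeum	CR	-2.19	-0.62	-0.33	0.21	0.07	-9.51
Liver intake	Eubacterium ventriosum	CC	0.84	8.90	-0.25	-2.20	0.97	-261.5
Milk type used: Never/rarely have milk	Bifidobacterium adolescentis	BCR	5.39	51.02	0.46	23.45	0.01	435.4
Milk type used: Never/rarely have milk	Streptococcus	CC	9.33	26.29	-0.17	-4.46	0.99	-47.79
Mineral and other dietary supplements: Calcium	Bacteroides ovatus	BR	4.05	2.99	0.16	0.48	0.05	11.85
Mineral and other dietary supplements: Calcium	Bacteroides ovatus	BCR	2.86	2.99	0.11	0.33	0.05	11.40
Mineral and other dietary supplements: Calcium	Bacteroides ovatus	BC	4.69	2.99	0.11	0.34	0.06	7.23
Mineral and other dietary supplements: Glucosamine	Sutterellaceae unclassified	BR	2.66	3.42	-0.24	-0.83	0.99	-31.11
Mineral and other dietary supplements: Zinc	Bifidobacterium adolescentis	BCR	3.86	-8.69	0.46	-3.99	0.99	-103.5
Single crust pastry intake	Coprococcus sp_ART55_1	CR	5.57	6.66	-0.29	-1.93	0.94	-34.57
Type of special diet followed: Gluten-free	Erysipelotrichaceae	CR	-6.55	-4.71	-0.22	1.05	0.05	-16.02
Type of special diet followed: Gluten-free	Streptococcus	CC	5.39	6.27	-0.17	-1.06	0.96	-19.74
Vitamin and mineral supplements: Multivitamins +/- minerals	Bacteroides ovatus	BC	2.62	2.03	0.11	0.23	0.04	8.82
Vitamin and mineral supplements: Multivitamins +/- minerals	Bacteroides ovatus	BCR	3.16	2.03	0.11	0.22	0.03	7.03
Vitamin and mineral supplements: Vitamin C	Coprococcus sp_ART55_1	CR	31.68	32.35	-0.29	-9.36	0.95	-29.54
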