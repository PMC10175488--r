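group	species	n_strains_matched	strains_single_hit	p1	p2	p3	p4	p5	richness_if_present_printed	richness_all_printed	prevalence_printed
Healthy-ICST	Bacteroides fragilis	157	13	24.7	6.6	0.3	0.0	0.0	1.2	0.39	31.7
Healthy-ICST	Bacteroides uniformis	174	32	19.1	4.6	0.3	0.0	0.0	1.2	0.29	24.0
Healthy-ICST	Bifidobacterium bifidum	163	12	29.8	13.2	0.4	0.0	0.0	1.3	0.58	43.4
Healthy-ICST	Bifidobacterium breve	150	34	24.5	7.6	0.4	0.0	0.0	1.3	0.41	32.5
Healthy-ICST	Bifidobacterium longum	388	90	22.1	34.7	13.2	1.5	0.1	1.9	1.37	71.5
Healthy-ICST	Bifidobacterium pseudocatenulatum	137	27	27.4	4.4	0.2	0.0	0.0	1.2	0.37	32.0
Healthy-ICST	Blautia wexlerae	160	24	21.5	6.9	0.9	0.1	0.0	1.3	0.38	29.4
Healthy-ICST	Enterobacter hormaechei	72	30	5.5	1.0	0.2	0.1	0.0	1.2	0.08	6.8
Healthy-ICST	Enterococcus faecalis	114	43	11.8	3.4	1.1	0.3	0.0	1.4	0.23	16.6
Healthy-ICST	Escherichia coli	1059	482	35.2	19.5	6.7	1.3	0.2	1.6	1.00	62.8
Healthy-ICST	Klebsiella michiganensis	76	38	5.2	0.6	0.0	0.0	0.0	1.1	0.06	5.7
Healthy-ICST	Klebsiella pneumoniae	233	107	10.3	3.6	0.6	0.1	0.0	1.4	0.20	14.5
Healthy-ICST	Prevotella copri	96	8	7.5	7.0	6.3	4.0	2.4	2.5	0.69	27.2
Healthy-ICST	Prevotella unknown species	59	1	3.0	4.4	5.9	3.7	2.4	2.9	0.57	19.5
Healthy-ICST	Ruminococcus gnavus	176	31	22.7	11.3	2.0	0.3	0.0	1.4	0.52	36.2
Healthy-ICST	Staphylococcus epidermidis	87	36	3.6	2.1	0.7	0.4	0.1	1.7	0.12	6.8
Healthy-ICST	Veillonella parvula	86	12	12.9	4.4	0.4	0.0	0.0	1.3	0.23	17.7
Mixed-ICST	Bacteroides fragilis	67	37	7.3	2.2	0.1	0.0	0.0	1.2	0.12	9.6
Mixed-ICST	Bacteroides uniformis	57	36	8.5	0.4	0.0	0.0	0.0	1.0	0.09	8.9
Mixed-ICST	Bifidobacterium bifidum	123	42	16.5	11.4	0.1	0.0	0.0	1.4	0.40	28.1
Mixed-ICST	Bifidobacterium breve	134	27	26.3	19.8	4.9	0.2	0.0	1.6	0.81	51.2
Mixed-ICST	Bifidobacterium longum	204	98	14.7	15.6	3.1	0.2	0.0	1.7	0.56	33.7
Mixed-ICST	Bifidobacterium pseudocatenulatum	57	22	8.1	2.4	0.7	0.2	0.0	1.4	0.16	11.4
Mixed-ICST	Blautia wexlerae	59	31	8.6	1.6	0.2	0.0	0.0	1.2	0.12	10.3
Mixed-ICST	Enterobacter hormaechei	94	23	32.8	10.0	0.9	0.7	0.0	1.3	0.58	44.3
Mixed-ICST	Enterococcus faecalis	95	36	33.5	11.7	2.1	0.2	0.1	1.4	0.64	47.5
Mixed-ICST	Escherichia coli	291	175	25.5	14.7	3.0	0.6	0.2	1.5	0.67	44.0
Mixed-ICST	Klebsiella michiganensis	36	14	8.5	1.6	0.0	0.0	0.0	1.2	0.12	10.0
Mixed-ICST	Klebsiella pneumoniae	119	55	18.0	5.9	0.5	0.0	0.1	1.3	0.32	24.5
Mixed-ICST	Prevotella copri	18	13	1.3	0.5	0.1	0.1	0.0	1.5	0.03	2.0
Mixed-ICST	Prevotella unknown species	13	13	0.2	0.3	0.1	0.0	0.0	1.9	0.01	0.6
Mixed-ICST	Ruminococcus gnavus	89	33	9.9	7.2	1.2	0.0	0.0	1.5	0.28	18.4
Mixed-ICST	Staphylococcus epidermidis	73	23	17.5	6.6	3.0	3.0	0.8	1.8	0.56	30.9
Mixed-ICST	Veillonella parvula	77	14	19.8	5.0	0.7	0.0	0.0	1.3	0.32	25.6
Unhealthy-ICST	Bacteroides fragilis	65	38	2.3	0.3	0.0	0.0	0.0	1.1	0.03	2.6
Unhealthy-ICST	Bacteroides uniformis	72	42	3.2	0.2	0.0	0.0	0.0	1.1	0.04	3.4
Unhealthy-ICST	Bifidobacterium bifidum	76	29	2.6	0.9	0.0	0.0	0.0	1.3	0.04	3.5
Unhealthy-ICST	Bifidobacterium breve	91	33	4.2	1.8	0.1	0.0	0.0	1.3	0.08	6.1
Unhealthy-ICST	Bifidobacterium longum	198	77	4.2	4.4	1.0	0.1	0.0	1.7	0.17	9.8
Unhealthy-ICST	Bifidobacterium pseudocatenulatum	37	19	1.8	0.3	0.0	0.0	0.0	1.1	0.02	2.1
Unhealthy-ICST	Blautia wexlerae	44	19	1.9	0.3	0.0	0.0	0.0	1.1	0.02	2.1
Unhealthy-ICST	Enterobacter hormaechei	92	27	10.0	1.3	0.0	0.0	0.0	1.1	0.13	11.4
Unhealthy-ICST	Enterococcus faecalis	158	45	33.6	12.4	3.0	0.4	0.0	1.4	0.69	49.4
Unhealthy-ICST	Escherichia coli	576	310	30.4	9.3	2.2	0.5	0.1	1.4	0.59	42.7
Unhealthy-ICST	Klebsiella michiganensis	92	18	15.2	2.4	0.1	0.0	0.0	1.2	0.20	17.7
Unhealthy-ICST	Klebsiella pneumoniae	257	78	19.7	8.1	1.9	0.6	0.0	1.5	0.44	30.2
Unhealthy-ICST	Prevotella copri	21	14	0.6	0.0	0.0	0.0	0.0	1.1	0.01	0.6
Unhealthy-ICST	Prevotella unknown species	15	9	0.2	0.1	0.0	0.0	0.0	1.4	0.00	0.3
Unhealthy-ICST	Ruminococcus gnavus	78	25	2.5	1.5	0.1	0.0	0.0	1.4	0.06	4.2
Unhealthy-ICST	Staphylococcus epidermidis	133	27	21.5	11.8	6.1	2.4	2.0	1.9	0.83	43.7
Unhealthy-ICST	Veillonella parvula	93	11	12.8	5.2	1.3	0.1	0.0	1.4	0.28	19.5
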