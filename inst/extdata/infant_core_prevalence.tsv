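taxon	n_present	prevalence	major_player_prevalence
Escherichia coli	5299	48.5	24.0
Bifidobacterium longum	3988	36.5	19.1
Enterococcus faecalis	3048	27.9	14.5
Bacteroides spp.	2808	25.7	1.1
Bifidobacterium breve	2692	24.6	8.3
Bifidobacterium bifidum	2330	21.3	7.3
Klebsiella michiganensis	2302	21.1	5.9
Bifidobacterium spp.	2282	20.9	0.8
Klebsiella pneumoniae	2088	19.1	8.5
Staphylococcus epidermidis	1934	17.7	9.2
Veillonella spp.	1873	17.1	2.1
Clostridium spp.	1836	16.8	1.0
Veillonella parvula	1802	16.5	6.7
Bacteroides uniformis	1780	16.3	4.0
Ruminococcus gnavus	1686	15.4	4.4
Collinsella aerofaciens	1660	15.2	2.1
Bifidobacterium pseudocatenulatum	1647	15.1	3.5
Blautia spp.	1587	14.5	0.3
Bacteroides fragilis	1543	14.1	5.1
Blautia wexlerae	1517	13.9	3.3
Phocaeicola vulgatus	1472	13.5	1.9
Flavonifractor plautii	1381	12.6	1.3
Parabacteroides distasonis	1374	12.6	2.8
Faecalibacterium spp.	1368	12.5	1.2
Phocaeicola dorei	1345	12.3	2.6
Enterobacter hormaechei	1342	12.3	6.1
Prevotella spp.	1297	11.9	8.2
Klebsiella spp.	1281	11.7	0.0
Prevotella copri	1278	11.7	8.0
Klebsiella variicola	1228	11.2	2.6
Veillonella atypica	1207	11.0	2.8
Klebsiella quasipneumoniae	1199	11.0	2.4
Streptococcus salivarius	1196	10.9	1.9
Ruminococcus spp.	1168	10.7	0.1
Streptococcus spp.	1168	10.7	1.2
Bifidobacterium catenulatum	1143	10.5	1.3
Faecalibacterium prausnitzii	1103	10.1	0.7
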