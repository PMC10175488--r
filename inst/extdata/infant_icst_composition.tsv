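icst	representative_species	n_infants	hi_percent	pi_percent	ri_percent	health_label
ICST-BI	Bifidobacterium longum	2198	68	19	14	Healthy
ICST-PR	Prevotella copri; Prevotella spp.	1981	42	12	46	Healthy
ICST-ES	Escherichia coli	1818	29	65	6	Unhealthy
ICST-BI/EN	Bifidobacterium breve; Enterobacter hormaechei	1216	50	49	1	Mixed
ICST-EN	Enterococcus faecalis	980	15	85	0	Unhealthy
ICST-KL/VE	Klebsiella michiganensis; Veillonella parvula	873	31	69	1	Unhealthy
ICST-KL	Klebsiella pneumoniae	735	17	83	0	Unhealthy
ICST-ST	Staphylococcus epidermidis	569	13	87	0	Unhealthy
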