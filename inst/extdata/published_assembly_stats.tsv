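species	level	number	n50_mb	shortest_bp	gc_percent	total_mb
xmaculatus	contig	67070	0.02	500	34.7	652
xcouchianus	contig	34765	0.06	200	35.4	648
xhellerii	contig	70798	0.03	200	34.6	657
xmaculatus	scaffold	20640	1.3	NA	NA	730
xcouchianus	scaffold	12015	1.8	NA	NA	711
xhellerii	scaffold	23897	1.6	NA	NA	741
xmaculatus	chromosome	24	29.4	NA	NA	724
xcouchianus	chromosome	24	29.3	NA	NA	708
xhellerii	chromosome	24	29.4	NA	NA	734
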