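category	xcouchianus	xhellerii
downstream	1542508	1942329
codon_indel	2467	2863
exon	211	230
intergenic	5007423	6594737
intron	4103306	5358720
non_synonymous_coding	84752	101178
splice_site	35823	44523
start_lost	116	133
stop_gained	805	945
stop_lost	314	445
synonymous_coding	140717	174526
upstream	1564218	1937840
utr3	243474	304241
utr5	51921	64017
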