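species	gene_models	n50_bp	mean_length_bp	total_mb
xmaculatus	20498	3615	2679	52.9
xcouchianus	20300	3609	2575	52.3
xhellerii	20325	3625	2581	52.5
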