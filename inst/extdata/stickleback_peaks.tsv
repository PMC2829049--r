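linkage_group	peak	width_mb	n_genes
I	1	1.0	52
IV	1	1.0	43
IV	2	1.1	31
IV	3	1.4	55
VII	1	0.8	42
VII	2	2.2	143
VIII	1	1.1	50
XI	1	1.0	55
XXI	1	2.6	119
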