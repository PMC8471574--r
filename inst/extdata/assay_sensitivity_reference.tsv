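species	lod_copies	loq_copies	efficiency_pct
Oncorhynchus keta	4.11	30	96.26
Oncorhynchus kisutch	8.44	45	95.15
Oncorhynchus masou	4.65	81	100.67
Oncorhynchus mykiss	10.38	34	106.33
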