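trait	chrom	start	end	gene_number
PH	Chr1	36420000	37240000	113
PH	Chr3	6060000	11030000	757
PH	Chr3	34420000	34490000	11
PH	Chr7	27310000	29690000	373
PH	Chr10	21460000	21940000	69
DH	Chr1	36420000	37240000	113
DH	Chr2	27240000	31070000	584
DH	Chr7	27520000	29690000	338
DH	Chr10	11130000	13470000	349
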