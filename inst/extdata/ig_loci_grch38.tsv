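locus	contig	start	end
IGH	chr14	105586437	106879844
IGK	chr2	88857361	90235368
IGL	chr22	22026076	22922913
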