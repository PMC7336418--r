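chrom	start	end	effect
chr21	95	186	0.4
chr21	303	398	0.4
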