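chrom	pos	ref	alt	freq
1	6000	G	T	0.05
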